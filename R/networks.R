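#' Canonical resting-state network labels
#'
#' The eight canonical cortical networks used to summarize seed connectivity:
#' visual (Vis), somatomotor (SomMot), dorsal attention (DAN), ventral
#' attention (VAN), limbic (Limbic), frontoparietal (FPN), temporoparietal
#' (TempPar) and default-mode (DMN). The order is fixed and global: it defines
#' spider-plot ordering and breaks ties in winner-take-all network assignment
#' (earlier label wins).
#'
#' @return Character vector of the eight network labels, in fixed order.
#' @export
#' @examples
#' network_labels()
network_labels <- function() {
  c("Vis", "SomMot", "DAN", "VAN", "Limbic", "FPN", "TempPar", "DMN")
}

#' @keywords internal
check_network <- function(network) {
  labs <- network_labels()
  if (!is.character(network) || !all(network %in% labs)) {
    stop("unknown network name(s): ",
         paste(setdiff(as.character(network), labs), collapse = ", "),
         "; must be one of ", paste(labs, collapse = ", "))
  }
  invisible(network)
}
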