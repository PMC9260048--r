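# File interchange. Internal vertex indexing is 1-based (R convention); all
# writers/readers convert explicitly to/from the 0-based convention used by
# GIFTI and the TSV face/parcellation tables.

gifti_header <- function(n_arrays) {
  sprintf('<?xml version="1.0" encoding="UTF-8"?>\n<GIFTI Version="1.0" NumberOfDataArrays="%d">\n', n_arrays)
}

gifti_data_array <- function(intent, datatype, data_text, dims) {
  dim_attrs <- paste(sprintf('Dim%d="%d"', seq_along(dims) - 1L, dims),
                     collapse = " ")
  paste0(
    sprintf('<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder" Dimensionality="%d" %s Encoding="ASCII" Endian="LittleEndian" ExternalFileName="" ExternalFileOffset="">\n',
            intent, datatype, length(dims), dim_attrs),
    "<Data>", data_text, "</Data>\n</DataArray>\n")
}

#' Write a surface mesh as GIFTI (.surf.gii)
#'
#' Writes a two-array GIFTI file (POINTSET + TRIANGLE) with ASCII-encoded
#' data. Face indices are converted to the 0-based GIFTI convention.
#'
#' @param mesh An `efnet_mesh`.
#' @param path Output path (conventionally `*.surf.gii`).
#' @return `path`, invisibly.
#' @export
write_gifti_surface <- function(mesh, path) {
  pts <- paste(apply(mesh$vertices, 1,
                     function(r) paste(format(r, digits = 17), collapse = " ")),
               collapse = "\n")
  tri <- paste(apply(mesh$faces - 1L, 1, paste, collapse = " "),
               collapse = "\n")
  xml <- paste0(
    gifti_header(2),
    gifti_data_array("NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32",
                     paste0("\n", pts, "\n"),
                     c(nrow(mesh$vertices), 3L)),
    gifti_data_array("NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
                     paste0("\n", tri, "\n"),
                     c(nrow(mesh$faces), 3L)),
    "</GIFTI>\n")
  writeLines(xml, path)
  invisible(path)
}

# decode one GIFTI DataArray node into a numeric vector (row-major)
decode_gifti_array <- function(node) {
  enc <- xml2::xml_attr(node, "Encoding")
  dtype <- xml2::xml_attr(node, "DataType")
  data_node <- xml2::xml_find_first(node, ".//Data")
  txt <- xml2::xml_text(data_node)
  if (enc == "ASCII") {
    vals <- as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
  } else if (enc %in% c("Base64Binary", "GZipBase64Binary")) {
    raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
    if (enc == "GZipBase64Binary") raw <- memDecompress(raw, type = "gzip")
    what <- if (grepl("FLOAT", dtype)) "double" else "integer"
    size <- if (dtype == "NIFTI_TYPE_FLOAT64") 8L else 4L
    vals <- readBin(raw, what, n = length(raw) / size, size = size,
                    endian = "little")
  } else {
    stop("unsupported GIFTI encoding: ", enc)
  }
  dims <- as.integer(c(xml2::xml_attr(node, "Dim0"),
                       xml2::xml_attr(node, "Dim1")))
  dims <- dims[!is.na(dims)]
  if (length(dims) == 2) {
    matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
  } else {
    vals
  }
}

#' Read a GIFTI surface (.surf.gii)
#'
#' Supports ASCII, Base64Binary and GZipBase64Binary encodings. Triangle
#' indices are converted from the 0-based file convention to 1-based.
#'
#' @param path Path to a GIFTI surface file.
#' @param hemisphere Hemisphere label to attach.
#' @return An `efnet_mesh`.
#' @export
read_gifti_surface <- function(path, hemisphere = "L") {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  intents <- xml2::xml_attr(arrays, "Intent")
  ip <- which(intents == "NIFTI_INTENT_POINTSET")
  it <- which(intents == "NIFTI_INTENT_TRIANGLE")
  if (length(ip) != 1 || length(it) != 1) {
    stop("GIFTI surface must contain one POINTSET and one TRIANGLE array")
  }
  vertices <- decode_gifti_array(arrays[[ip]])
  faces <- decode_gifti_array(arrays[[it]]) + 1L
  surface_mesh(vertices, faces, hemisphere)
}

#' Write a per-vertex scalar map as GIFTI (.func.gii)
#'
#' @param values Numeric per-vertex values.
#' @param path Output path (conventionally `*.func.gii`).
#' @return `path`, invisibly.
#' @export
write_gifti_metric <- function(values, path) {
  xml <- paste0(
    gifti_header(1),
    gifti_data_array("NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32",
                     paste0("\n",
                            paste(format(as.numeric(values), digits = 17),
                                  collapse = "\n"), "\n"),
                     length(values)),
    "</GIFTI>\n")
  writeLines(xml, path)
  invisible(path)
}

#' Read a per-vertex scalar map from GIFTI (.func.gii)
#'
#' @param path Path to a GIFTI metric file.
#' @return Numeric vector of per-vertex values.
#' @export
read_gifti_metric <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(arrays) < 1) stop("GIFTI metric contains no data array")
  as.numeric(decode_gifti_array(arrays[[1]]))
}

#' Write a mesh as a plain-text TSV pair
#'
#' Fallback interchange format: `<stem>_vertices.tsv` (columns x, y, z) and
#' `<stem>_faces.tsv` (columns v0, v1, v2; 0-based indices).
#'
#' @param mesh An `efnet_mesh`.
#' @param stem Path stem (no extension).
#' @return Character vector of the two paths written, invisibly.
#' @export
write_mesh_tsv <- function(mesh, stem) {
  vp <- paste0(stem, "_vertices.tsv")
  fp <- paste0(stem, "_faces.tsv")
  v <- as.data.frame(mesh$vertices)
  names(v) <- c("x", "y", "z")
  f <- as.data.frame(mesh$faces - 1L)
  names(f) <- c("v0", "v1", "v2")
  utils::write.table(v, vp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(f, fp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vp, fp))
}

#' Read a mesh from a plain-text TSV pair
#'
#' @param stem Path stem used by [write_mesh_tsv()].
#' @param hemisphere Hemisphere label to attach.
#' @return An `efnet_mesh`.
#' @export
read_mesh_tsv <- function(stem, hemisphere = "L") {
  v <- utils::read.table(paste0(stem, "_vertices.tsv"), header = TRUE,
                         sep = "\t")
  f <- utils::read.table(paste0(stem, "_faces.tsv"), header = TRUE,
                         sep = "\t")
  surface_mesh(as.matrix(v), as.matrix(f) + 1L, hemisphere)
}

#' Write/read a scalar map as single-column TSV
#'
#' @param values Numeric per-vertex values.
#' @param path TSV path.
#' @return `path` (write) or numeric vector (read).
#' @export
write_scalar_tsv <- function(values, path) {
  utils::write.table(data.frame(value = as.numeric(values)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scalar_tsv
#' @export
read_scalar_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")$value
}

#' Write a parcellation as two TSV tables
#'
#' `<stem>_vertices.tsv` maps 0-based `vertex_id` to `parcel_id`;
#' `<stem>_networks.tsv` maps `parcel_id` to `network_name` (one of the eight
#' fixed labels).
#'
#' @param parcellation An `efnet_parcellation`.
#' @param stem Path stem.
#' @return Character vector of the two paths, invisibly.
#' @export
write_parcellation_tsv <- function(parcellation, stem) {
  vp <- paste0(stem, "_vertices.tsv")
  np <- paste0(stem, "_networks.tsv")
  utils::write.table(
    data.frame(vertex_id = seq_along(parcellation$vertex_parcel) - 1L,
               parcel_id = parcellation$vertex_parcel),
    vp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(parcel_id = as.integer(names(parcellation$parcel_network)),
               network_name = unname(parcellation$parcel_network)),
    np, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vp, np))
}

#' Read a parcellation from its two TSV tables
#'
#' @param stem Path stem used by [write_parcellation_tsv()].
#' @return An `efnet_parcellation` (without center information).
#' @export
read_parcellation_tsv <- function(stem) {
  v <- utils::read.table(paste0(stem, "_vertices.tsv"), header = TRUE,
                         sep = "\t")
  n <- utils::read.table(paste0(stem, "_networks.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
  check_network(n$network_name)
  v <- v[order(v$vertex_id), ]
  if (!identical(as.integer(v$vertex_id), seq_len(nrow(v)) - 1L)) {
    stop("vertex_id column must enumerate 0..n-1")
  }
  pn <- stats::setNames(n$network_name, as.character(n$parcel_id))
  p <- structure(list(vertex_parcel = as.integer(v$parcel_id),
                      parcel_network = pn, centers = NULL),
                 class = "efnet_parcellation")
  check_parcellation(p)
  p
}

#' Write a dense connectome as a binary container with JSON sidecar
#'
#' Row-major little-endian float64 values in `<stem>.bin`, with
#' `<stem>.json` recording shape, dtype and byte order. A gzipped-TSV
#' alternative is available via `format = "tsv.gz"`.
#'
#' @param m Connectome matrix.
#' @param stem Path stem (no extension).
#' @param format `"bin"` (default) or `"tsv.gz"`.
#' @return Path(s) written, invisibly.
#' @export
write_connectome <- function(m, stem, format = c("bin", "tsv.gz")) {
  format <- match.arg(format)
  if (format == "tsv.gz") {
    path <- paste0(stem, ".tsv.gz")
    con <- gzfile(path, "w")
    on.exit(close(con))
    utils::write.table(m, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  bin <- paste0(stem, ".bin")
  side <- paste0(stem, ".json")
  con <- file(bin, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(m)), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(shape = dim(m), dtype = "float64", order = "row-major",
         endian = "little", vertex_order = "mesh"),
    side, auto_unbox = TRUE)
  invisible(c(bin, side))
}

#' Read a dense connectome written by [write_connectome()]
#'
#' @param stem Path stem.
#' @param format `"bin"` or `"tsv.gz"`.
#' @return Connectome matrix.
#' @export
read_connectome <- function(stem, format = c("bin", "tsv.gz")) {
  format <- match.arg(format)
  if (format == "tsv.gz") {
    m <- as.matrix(utils::read.table(gzfile(paste0(stem, ".tsv.gz")),
                                     sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    return(m)
  }
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  n <- as.integer(meta$shape)
  con <- file(paste0(stem, ".bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = prod(n), size = 8,
                  endian = meta$endian)
  matrix(vals, nrow = n[1], ncol = n[2], byrow = meta$order == "row-major")
}

#' Write a cohort directory
#'
#' Writes the template mesh (GIFTI + TSV), parcellation TSVs, template and
#' per-subject E-field maps (GIFTI metric), per-subject connectomes (binary
#' container + JSON sidecar, unless `write_connectomes = FALSE`), and a
#' manifest JSON recording the spec and file inventory.
#'
#' @param cohort An `efnet_cohort`.
#' @param dir Output directory (created if absent).
#' @param write_connectomes Write per-subject and group connectome binaries
#'   (can be large); default `TRUE`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_connectomes = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gifti_surface(cohort$mesh, file.path(dir, "template.surf.gii"))
  write_mesh_tsv(cohort$mesh, file.path(dir, "template"))
  write_parcellation_tsv(cohort$parcellation, file.path(dir, "parcellation"))
  for (tg in names(cohort$template_efield)) {
    write_gifti_metric(cohort$template_efield[[tg]],
                       file.path(dir, sprintf("template_efield_%s.func.gii", tg)))
  }
  rows <- list()
  for (sub in cohort$subjects) {
    for (tg in names(sub$efield)) {
      p <- file.path(dir, sprintf("%s_efield_%s.func.gii", sub$subject_id, tg))
      write_gifti_metric(sub$efield[[tg]], p)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = sub$subject_id, kind = "efield", target = tg,
        file = basename(p))
    }
    if (write_connectomes) {
      stem <- file.path(dir, paste0(sub$subject_id, "_fc"))
      write_connectome(sub$fc, stem)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = sub$subject_id, kind = "fc", target = "",
        file = basename(paste0(stem, ".bin")))
    }
  }
  if (write_connectomes) {
    write_connectome(cohort$group_fc, file.path(dir, "group_fc"))
  }
  manifest <- data.frame(do.call(rbind, rows))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(unclass(cohort$spec),
      list(targets = names(cohort$placements),
           n_vertices = n_vertices(cohort$mesh))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}
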