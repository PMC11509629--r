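## Plain-text force-curve files: two numeric columns (depth, force) after
## a commented header block of "# key: value" lines. Vendor formats are
## out of scope; users export to text first.

depth_unit_factors <- c(m = 1, mm = 1e-3, um = 1e-6, "µm" = 1e-6,
                        nm = 1e-9)
force_unit_factors <- c(N = 1, mN = 1e-3, uN = 1e-6, "µN" = 1e-6,
                        nN = 1e-9, pN = 1e-12)

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write a force curve to a plain-text file
#'
#' Writes a commented `# key: value` header (units, geometry, material and
#' any curve metadata) followed by two tab-separated numeric columns
#' (depth, force). [read_force_curve()] restores the curve including its
#' metadata.
#'
#' @param curve A [force_curve()].
#' @param path Output file path.
#' @param units Named character vector `c(depth = , force = )`; one of
#'   m/mm/um/nm and N/mN/uN/nN/pN. Defaults to SI (m, N).
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path,
                              units = c(depth = "m", force = "N")) {
  du <- depth_unit_factors[[units[["depth"]]]]
  fu <- force_unit_factors[[units[["force"]]]]
  hdr <- c("# afmblunt force curve",
           paste0("# depth_unit: ", units[["depth"]]),
           paste0("# force_unit: ", units[["force"]]))
  g <- curve_geometry(curve)
  if (!is.null(g)) {
    hdr <- c(hdr, paste0("# family: ", g$family))
    if (is.finite(g$R)) hdr <- c(hdr, paste0("# R_m: ", fmt_num(g$R)))
    if (is.finite(g$theta))
      hdr <- c(hdr, paste0("# theta_deg: ", fmt_num(g$theta * 180 / pi)))
    if (!is.na(g$k)) hdr <- c(hdr, paste0("# k: ", g$k))
  }
  m <- curve_material(curve)
  if (!is.null(m))
    hdr <- c(hdr, paste0("# E_Pa: ", fmt_num(m$E)),
             paste0("# nu: ", fmt_num(m$nu)))
  meta <- curve_meta(curve)
  for (key in names(meta)) {
    v <- meta[[key]]
    if (length(v) == 1L && (is.character(v) || is.numeric(v)))
      hdr <- c(hdr, paste0("# ", key, ": ",
                           if (is.numeric(v)) fmt_num(v) else v))
  }
  body <- paste(fmt_num(curve$h / du), fmt_num(curve$force / fu),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

parse_header <- function(lines) {
  kv <- list()
  for (ln in lines) {
    txt <- sub("^#\\s*", "", ln)
    if (!grepl(":", txt, fixed = TRUE)) next
    key <- trimws(sub(":.*$", "", txt))
    val <- trimws(sub("^[^:]*:\\s*", "", txt))
    if (nzchar(key)) kv[[key]] <- val
  }
  kv
}

num_or_char <- function(x) {
  y <- suppressWarnings(as.numeric(x))
  if (is.na(y)) x else y
}

#' Read a force curve from a plain-text file
#'
#' Accepts two numeric columns (depth, force) separated by whitespace,
#' tabs or commas, with optional `# key: value` header lines. Units must
#' be declared in the header (`depth_unit`, `force_unit`) or supplied via
#' `units`. Rows with negative depth (pre-contact) are dropped with a
#' message; rows are stably sorted by increasing depth. Geometry and
#' material headers written by [write_force_curve()] are restored; unknown
#' header keys are preserved in the curve metadata.
#'
#' @param path Input file.
#' @param units Optional named character vector `c(depth = , force = )`
#'   overriding (or standing in for) the header units.
#' @return A [force_curve()] in SI units.
#' @export
read_force_curve <- function(path, units = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_hdr <- grepl("^\\s*#", lines)
  kv <- parse_header(lines[is_hdr])
  data_lines <- trimws(lines[!is_hdr])
  data_lines <- data_lines[nzchar(data_lines)]
  if (length(data_lines) == 0L)
    stop("no data rows in ", path, call. = FALSE)

  fields <- strsplit(data_lines, "[,\t ]+")
  bad <- vapply(fields, length, integer(1)) < 2L
  if (any(bad)) stop("unparseable rows in ", path, call. = FALSE)
  h <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  Fv <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (any(is.na(h)) || any(is.na(Fv)))
    stop("non-numeric values in ", path, call. = FALSE)

  du_name <- if (!is.null(units)) units[["depth"]] else kv[["depth_unit"]]
  fu_name <- if (!is.null(units)) units[["force"]] else kv[["force_unit"]]
  if (is.null(du_name) || is.null(fu_name))
    stop("units not declared in ", path,
         " and no `units` override given", call. = FALSE)
  if (!du_name %in% names(depth_unit_factors))
    stop("unknown depth unit '", du_name, "'", call. = FALSE)
  if (!fu_name %in% names(force_unit_factors))
    stop("unknown force unit '", fu_name, "'", call. = FALSE)
  h <- h * depth_unit_factors[[du_name]]
  Fv <- Fv * force_unit_factors[[fu_name]]

  neg <- h < 0
  if (any(neg)) {
    message("dropping ", sum(neg), " pre-contact row(s) with negative depth")
    h <- h[!neg]; Fv <- Fv[!neg]
  }
  if (length(h) < 5L)
    stop("fewer than 5 valid points in ", path, call. = FALSE)
  ord <- order(h)  # stable
  h <- h[ord]; Fv <- Fv[ord]

  geometry <- NULL
  if (!is.null(kv[["family"]])) {
    geometry <- tryCatch(
      indenter_geometry(kv[["family"]],
                        R = if (!is.null(kv[["R_m"]]))
                          as.numeric(kv[["R_m"]]),
                        theta_deg = if (!is.null(kv[["theta_deg"]]))
                          as.numeric(kv[["theta_deg"]]),
                        k = if (!is.null(kv[["k"]]))
                          as.integer(kv[["k"]])),
      error = function(e) NULL)
  }
  mat <- NULL
  if (!is.null(kv[["E_Pa"]]) && !is.null(kv[["nu"]]))
    mat <- tryCatch(material(as.numeric(kv[["E_Pa"]]),
                             as.numeric(kv[["nu"]])),
                    error = function(e) NULL)

  known <- c("depth_unit", "force_unit", "family", "R_m", "theta_deg", "k",
             "E_Pa", "nu", "afmblunt force curve")
  meta <- lapply(kv[setdiff(names(kv), known)], num_or_char)

  force_curve(h, Fv, geometry = geometry, material = mat, meta = meta)
}
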