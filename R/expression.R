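#' Expression matrix container
#'
#' An `expr_mat` is a tibble whose first column is `probe_id` and whose
#' remaining columns are samples, holding log2 expression values. Sample
#' roles (`"tumour"` or `"control"`) and a free-text platform tag travel as
#' attributes, so the object pipes through dplyr verbs while matrix maths
#' uses [expr_values()].
#'
#' @param values Numeric matrix, probes in rows and samples in columns.
#' @param probe_ids Character vector of unique probe identifiers.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param sample_role Character vector in `{"tumour", "control"}`, one per
#'   sample (recycled if length 1).
#' @param platform Free-text platform tag.
#' @return A tibble of class `expr_mat`.
#' @export
expression_matrix <- function(values, probe_ids, sample_ids,
                              sample_role = "tumour", platform = "unknown") {
  values <- as.matrix(values)
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe ids: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (nrow(values) != length(probe_ids) || ncol(values) != length(sample_ids)) {
    stop("matrix dimensions (", nrow(values), " x ", ncol(values),
         ") do not match id lists (", length(probe_ids), " probes, ",
         length(sample_ids), " samples)")
  }
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (length(sample_role) == 1) sample_role <- rep(sample_role, length(sample_ids))
  if (length(sample_role) != length(sample_ids)) {
    stop("sample_role must have one entry per sample")
  }
  if (!all(sample_role %in% c("tumour", "control"))) {
    stop("sample_role entries must be 'tumour' or 'control'")
  }
  out <- tibble::as_tibble(as.data.frame(values, check.names = FALSE,
                                         row.names = NULL))
  names(out) <- sample_ids
  out <- dplyr::bind_cols(tibble::tibble(probe_id = as.character(probe_ids)), out)
  attr(out, "sample_role") <- stats::setNames(sample_role, sample_ids)
  attr(out, "platform") <- platform
  attr(out, "standardized") <- FALSE
  class(out) <- c("expr_mat", class(out))
  out
}

#' @export
print.expr_mat <- function(x, ...) {
  cat("<expr_mat> ", nrow(x), " probes x ", ncol(x) - 1, " samples (",
      sum(expr_roles(x) == "tumour"), " tumour, ",
      sum(expr_roles(x) == "control"), " control), platform: ",
      attr(x, "platform"),
      if (isTRUE(attr(x, "standardized"))) ", standardized" else "",
      "\n", sep = "")
  NextMethod()
}

#' Accessors for expr_mat objects
#'
#' `expr_values()` returns the numeric probe x sample matrix with dimnames;
#' `expr_probes()` and `expr_samples()` the identifier vectors;
#' `expr_roles()` the named role vector; `tumour_ids()` / `control_ids()`
#' the sample ids of each role.
#'
#' @param x An `expr_mat`.
#' @return See individual descriptions.
#' @export
expr_values <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$probe_id
  m
}

#' @rdname expr_values
#' @export
expr_probes <- function(x) x$probe_id

#' @rdname expr_values
#' @export
expr_samples <- function(x) names(x)[-1]

#' @rdname expr_values
#' @export
expr_roles <- function(x) attr(x, "sample_role")[expr_samples(x)]

#' @rdname expr_values
#' @export
tumour_ids <- function(x) names(which(expr_roles(x) == "tumour"))

#' @rdname expr_values
#' @export
control_ids <- function(x) names(which(expr_roles(x) == "control"))

#' Subset an expression matrix by probes and/or samples
#'
#' @param x An `expr_mat`.
#' @param probes Character vector of probe ids to keep (default all), in the
#'   order given.
#' @param samples Character vector of sample ids to keep (default all).
#' @return An `expr_mat` restricted to the requested rows/columns.
#' @export
expr_subset <- function(x, probes = NULL, samples = NULL) {
  if (is.null(probes)) probes <- expr_probes(x)
  if (is.null(samples)) samples <- expr_samples(x)
  missing_p <- setdiff(probes, expr_probes(x))
  if (length(missing_p)) {
    stop("probes absent from expression matrix: ",
         paste(missing_p, collapse = ", "))
  }
  missing_s <- setdiff(samples, expr_samples(x))
  if (length(missing_s)) {
    stop("samples absent from expression matrix: ",
         paste(missing_s, collapse = ", "))
  }
  m <- expr_values(x)[probes, samples, drop = FALSE]
  out <- expression_matrix(m, probes, samples,
                           sample_role = unname(expr_roles(x)[samples]),
                           platform = attr(x, "platform"))
  attr(out, "standardized") <- attr(x, "standardized")
  out
}

#' Long-format view of an expression matrix
#'
#' @param x An `expr_mat`.
#' @param ... Unused.
#' @return A tibble with columns `probe_id`, `sample_id`, `role`, `value`.
#' @method tidy expr_mat
#' @export
tidy.expr_mat <- function(x, ...) {
  roles <- expr_roles(x)
  out <- tidyr::pivot_longer(tibble::as_tibble(unclass(x)), -"probe_id",
                             names_to = "sample_id", values_to = "value")
  out$role <- unname(roles[out$sample_id])
  out[, c("probe_id", "sample_id", "role", "value")]
}

#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample ids and a first column of probe ids. The
#' role map is a two-column tab-separated file (`sample_id`, `role`) listing
#' every sample; roles are `tumour` or `control`.
#'
#' @param path Path to the expression matrix file.
#' @param role_map_path Path to the sample role map. May be `NULL`, in which
#'   case every sample is treated as a tumour.
#' @param platform Platform tag attached to the result.
#' @return An `expr_mat` with file row/column order preserved.
#' @export
read_expression <- function(path, role_map_path = NULL, platform = "unknown") {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2) stop("expression file needs a probe column plus samples")
  probe_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-numeric expression value at probe '", probe_ids[bad[1, 1]],
         "', sample '", sample_ids[bad[1, 2]], "'")
  }
  if (anyNA(num)) {
    bad_na <- which(is.na(num), arr.ind = TRUE)
    stop("missing expression value at probe '", probe_ids[bad_na[1, 1]],
         "', sample '", sample_ids[bad_na[1, 2]],
         "'; missing values are rejected, not imputed")
  }
  if (is.null(role_map_path)) {
    roles <- rep("tumour", length(sample_ids))
  } else {
    rm_tbl <- utils::read.delim(role_map_path, header = TRUE, sep = "\t",
                                colClasses = "character")
    if (!all(c("sample_id", "role") %in% names(rm_tbl))) {
      stop("role map needs columns sample_id and role")
    }
    missing <- setdiff(sample_ids, rm_tbl$sample_id)
    if (length(missing)) {
      stop("samples missing from role map: ", paste(missing, collapse = ", "))
    }
    roles <- rm_tbl$role[match(sample_ids, rm_tbl$sample_id)]
  }
  expression_matrix(num, probe_ids, sample_ids, sample_role = roles,
                    platform = platform)
}

#' Write an expression matrix as tab-separated text
#'
#' Values are written with full round-trip precision (shortest decimal
#' representation that restores the double exactly).
#'
#' @param x An `expr_mat`.
#' @param path Output path.
#' @param role_map_path Optional path for the companion role map.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, role_map_path = NULL) {
  m <- expr_values(x)
  df <- data.frame(probe_id = rownames(m),
                   apply(m, 2, function(col) vapply(col, format_num, "")),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(role_map_path)) {
    roles <- expr_roles(x)
    utils::write.table(
      data.frame(sample_id = names(roles), role = unname(roles)),
      role_map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# shortest decimal string that round-trips a double
format_num <- function(v) {
  for (d in 1:17) {
    s <- formatC(v, digits = d, format = "g")
    if (as.numeric(s) == v) return(s)
  }
  formatC(v, digits = 17, format = "g")
}

#' Read a UCSC-style cytoband file
#'
#' Five tab-separated columns without header: chromosome, start, end, band
#' name, Giemsa stain (ignored). Coordinates are 0-based half-open, the UCSC
#' convention, so band length is `end - start`.
#'
#' @param path Path to the cytoband file.
#' @return A tibble with columns `chrom`, `start_bp`, `end_bp`, `band_name`,
#'   `stain`, `cytoband` (chrom + band name) and `length_bp`.
#' @export
read_cytobands <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no cytobands in file '", path, "'")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4)) {
    stop("malformed cytoband line ", which(nf < 4)[1], " in '", path, "'")
  }
  tbl <- tibble::tibble(
    chrom = vapply(parts, `[[`, "", 1),
    start_bp = suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2))),
    end_bp = suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3))),
    band_name = vapply(parts, `[[`, "", 4),
    stain = vapply(parts, function(p) if (length(p) >= 5) p[[5]] else "", "")
  )
  if (anyNA(tbl$start_bp) || anyNA(tbl$end_bp)) {
    bad <- which(is.na(tbl$start_bp) | is.na(tbl$end_bp))[1]
    stop("malformed cytoband line ", bad, " in '", path,
         "': non-numeric coordinates")
  }
  if (any(tbl$end_bp <= tbl$start_bp)) {
    bad <- which(tbl$end_bp <= tbl$start_bp)[1]
    stop("cytoband line ", bad, ": end (", tbl$end_bp[bad],
         ") must exceed start (", tbl$start_bp[bad], ")")
  }
  dup <- duplicated(paste(tbl$chrom, tbl$band_name))
  if (any(dup)) {
    stop("duplicate band name within chromosome: ",
         paste(unique(paste0(tbl$chrom, tbl$band_name)[dup]), collapse = ", "))
  }
  tbl$cytoband <- paste0(tbl$chrom, tbl$band_name)
  tbl$length_bp <- tbl$end_bp - tbl$start_bp
  tbl
}
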