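# Plain-TSV readers and writers for every pipeline artifact.
#
# Format: '#'-prefixed "key: value" metadata lines, a tab-separated header
# row, then data rows.  Floating-point values are written with 17
# significant digits so that write -> read round-trips values exactly; no
# timestamps are written, so reruns with identical inputs produce
# byte-identical files.

.fmt_cell <- function(x) {
  if (is.na(x)) return("NA")
  if (is.numeric(x) && !is.integer(x)) return(sprintf("%.17g", x))
  as.character(x)
}

.write_artifact <- function(df, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta)) {
    v <- meta[[k]]
    writeLines(paste0("# ", k, ": ", paste(vapply(v, .fmt_cell, ""),
                                           collapse = ",")), con)
  }
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    cols <- lapply(df, function(col) vapply(col, .fmt_cell, ""))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

.read_artifact <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (l in lines[is_meta]) {
    l <- sub("^#\\s*", "", l)
    k <- sub(":.*$", "", l)
    v <- sub("^[^:]*:\\s*", "", l)
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    meta[[k]] <- if (length(parts) > 0 && !anyNA(num)) num else v
  }
  body <- lines[!is_meta & nzchar(lines)]
  if (length(body) < 1) stop("no table in ", path)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  nfield <- lengths(rows)
  bad <- which(nfield != length(header))
  if (length(bad) > 0) {
    lineno <- which(!is_meta & nzchar(lines))[1 + bad[1]]
    stop("malformed row at line ", lineno, " of ", path, ": expected ",
         length(header), " fields, found ", nfield[bad[1]])
  }
  cols <- lapply(seq_along(header), function(j) {
    v <- vapply(rows, `[[`, "", j)
    v[v == "NA"] <- NA
    num <- suppressWarnings(as.numeric(v))
    if (all(is.na(num) == is.na(v))) {
      num
    } else if (all(v %in% c("TRUE", "FALSE", NA))) {
      as.logical(v)
    } else v
  })
  names(cols) <- header
  df <- as.data.frame(cols, optional = TRUE,
                      stringsAsFactors = FALSE)
  # zero-row table
  if (length(rows) == 0) df <- df[0, , drop = FALSE]
  list(meta = meta, data = df)
}

#' Read / write pipeline artifacts as annotated TSV
#'
#' Every artifact travels as a plain tab-separated file with `#`-prefixed
#' `key: value` metadata lines.  Floats are written at 17 significant
#' digits, so `write_* %>% read_*` round-trips values exactly; comment lines
#' are ignored on read and malformed rows raise an error naming the line.
#'
#' @param series,pmf,result,path,chain,frames the object to write.
#' @param file file path.
#' @return Readers return the reconstructed object; writers return `file`
#'   invisibly.
#' @name artifact_io
NULL

#' @rdname artifact_io
#' @export
write_sample_series <- function(series, file) {
  w <- series$window
  df <- data.frame(step = seq_len(nrow(series$values)) * series$stride)
  for (j in seq_len(ncol(series$values)))
    df[[colnames(series$values)[j]]] <- series$values[, j]
  .write_artifact(df, file, meta = list(
    window_id = w$window_id, centers = w$centers,
    k_equil = w$k_equil, k_prod = w$k_prod,
    n_equil = w$n_equil, n_prod = w$n_prod,
    temperature = w$temperature, seed = w$seed,
    stride = series$stride, acceptance = series$acceptance))
}

#' @rdname artifact_io
#' @export
read_sample_series <- function(file) {
  a <- .read_artifact(file)
  m <- a$meta
  vals <- as.matrix(a$data[, setdiff(names(a$data), "step"), drop = FALSE])
  w <- bias_window(m$window_id, m$centers, k_equil = m$k_equil,
                   k_prod = m$k_prod, n_equil = m$n_equil,
                   n_prod = m$n_prod, temperature = m$temperature,
                   seed = m$seed)
  structure(list(window_id = w$window_id, values = vals,
                 stride = as.integer(m$stride), window = w,
                 temperature = m$temperature,
                 acceptance = if (is.null(m$acceptance)) NA_real_
                              else m$acceptance),
            class = "sample_series")
}

#' @rdname artifact_io
#' @export
write_pmf_grid <- function(pmf, file) {
  C <- .bin_center_matrix(pmf$centers)
  d <- ncol(C)
  df <- as.data.frame(C)
  names(df) <- paste0("center", seq_len(d))
  df$F <- pmf$F
  if (!is.null(pmf$error)) df$error <- pmf$error
  df$mask <- pmf$mask
  meta <- list(temperature = pmf$temperature,
               converged = pmf$converged, iterations = pmf$iterations)
  for (j in seq_len(d)) meta[[paste0("edges", j)]] <- pmf$edges[[j]]
  if (!is.null(pmf$f_windows)) meta$f_windows <- pmf$f_windows
  .write_artifact(df, file, meta = meta)
}

#' @rdname artifact_io
#' @export
read_pmf_grid <- function(file) {
  a <- .read_artifact(file)
  m <- a$meta
  edges <- list()
  j <- 1
  while (!is.null(m[[paste0("edges", j)]])) {
    edges[[j]] <- m[[paste0("edges", j)]]
    j <- j + 1
  }
  pmf_grid(edges, a$data$F, mask = a$data$mask,
           error = a$data$error, f_windows = m$f_windows,
           temperature = m$temperature,
           converged = isTRUE(m$converged == "TRUE") || isTRUE(m$converged),
           iterations = if (is.null(m$iterations)) 0L else m$iterations)
}

#' @rdname artifact_io
#' @export
write_scan_result <- function(result, file) {
  .write_artifact(as.data.frame(result), file, meta = list(
    axes = paste(attr(result, "axes"), collapse = ","),
    grad_tol = attr(result, "grad_tol"),
    restraint_k = attr(result, "restraint_k"),
    direction = attr(result, "direction")))
}

#' @rdname artifact_io
#' @export
read_scan_result <- function(file) {
  a <- .read_artifact(file)
  structure(a$data, class = c("scan_result", "data.frame"),
            axes = a$meta$axes, grad_tol = a$meta$grad_tol,
            restraint_k = a$meta$restraint_k, direction = a$meta$direction)
}

#' @rdname artifact_io
#' @export
write_grid_path <- function(path, file) {
  .write_artifact(as.data.frame(path), file, meta = list(
    total_weight = attr(path, "total_weight"),
    criterion = attr(path, "criterion")))
}

#' @rdname artifact_io
#' @export
read_grid_path <- function(file) {
  a <- .read_artifact(file)
  structure(a$data, class = c("grid_path", "data.frame"),
            total_weight = a$meta$total_weight,
            criterion = a$meta$criterion)
}

#' @rdname artifact_io
#' @export
write_chain_path <- function(chain, file) {
  X <- chain$points
  df <- data.frame(index = seq_len(nrow(X)))
  for (j in seq_len(ncol(X))) df[[paste0("x", j)]] <- X[, j]
  if (!is.null(chain$energies)) df$energy <- chain$energies
  df$fixed <- chain$fixed
  .write_artifact(df, file)
}

#' @rdname artifact_io
#' @export
read_chain_path <- function(file) {
  a <- .read_artifact(file)
  xcols <- grep("^x[0-9]+$", names(a$data), value = TRUE)
  cp <- chain_path(as.matrix(a$data[, xcols, drop = FALSE]),
                   energies = a$data$energy)
  cp$fixed <- a$data$fixed
  cp
}

#' @rdname artifact_io
#' @export
write_distance_frames <- function(frames, file) {
  .write_artifact(frames, file)
}

#' @rdname artifact_io
#' @export
read_distance_frames <- function(file) {
  .read_artifact(file)$data
}
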