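#' Construct a landmark curve
#'
#' A `landmark_curve` holds the ordered 2D semi-landmarks of one open suture
#' outline. Point order encodes the suture path from one endpoint to the
#' other; the curve is never re-sorted by coordinate.
#'
#' @param specimen_id Character label identifying the specimen/suture.
#' @param coords Two-column numeric matrix (x, y), one row per semi-landmark,
#'   in arbitrary planar units.
#' @return An object of class `landmark_curve` with elements `specimen_id`,
#'   `coords` and `n_points`.
#' @examples
#' landmark_curve("s1", cbind(0:2, c(0, 1, 0)))
#' @export
landmark_curve <- function(specimen_id, coords) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 2)
    stop("coords must be a numeric matrix with two columns (x, y)")
  if (nrow(coords) < 2)
    stop("a landmark curve needs at least 2 points (specimen ",
         specimen_id, " has ", nrow(coords), ")")
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in specimen ", specimen_id)
  dimnames(coords) <- list(NULL, c("x", "y"))
  structure(
    list(specimen_id = as.character(specimen_id),
         coords = coords,
         n_points = nrow(coords)),
    class = "landmark_curve")
}

#' @export
print.landmark_curve <- function(x, ...) {
  cat("<landmark_curve> ", x$specimen_id, ": ", x$n_points, " points\n", sep = "")
  invisible(x)
}

#' Read semi-landmark curves from a TPS or CSV file
#'
#' Two dialects are supported. `tps` is the classical landmark format: records
#' of `LM=<k>` followed by k lines of `x y`, closed by `ID=<label>`. `csv` has
#' columns `specimen_id, point_index, x, y`; rows are ordered by
#' `point_index` within specimen.
#'
#' @param path Path to the landmark file.
#' @param dialect Either `"tps"` or `"csv"`.
#' @return A named list of [landmark_curve] objects, in file order.
#' @seealso [write_landmarks()], [resample_equidistant()]
#' @export
read_landmarks <- function(path, dialect = c("tps", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  curves <- switch(dialect,
    tps = read_landmarks_tps(path),
    csv = read_landmarks_csv(path))
  ids <- vapply(curves, function(cv) cv$specimen_id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate specimen_id in ", path, ": ", paste(unique(dup), collapse = ", "))
  names(curves) <- ids
  curves
}

read_landmarks_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  curves <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (lines[i] == "") { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE))
      stop("TPS parse error at line ", i, ": expected 'LM=' record, got '", lines[i], "'")
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", lines[i], ignore.case = TRUE)))
    if (is.na(k) || k < 2)
      stop("TPS validation error at line ", i, ": LM count must be an integer >= 2")
    if (i + k > length(lines))
      stop("TPS parse error: record at line ", i, " declares ", k,
           " landmarks but the file ends early")
    coord_lines <- lines[(i + 1L):(i + k)]
    xy <- t(vapply(seq_along(coord_lines), function(j) {
      v <- suppressWarnings(as.numeric(strsplit(coord_lines[j], "[,[:space:]]+")[[1]]))
      if (length(v) != 2 || anyNA(v))
        stop("TPS parse error at line ", i + j, ": expected two numbers, got '",
             coord_lines[j], "'")
      v
    }, numeric(2)))
    i <- i + k + 1L
    id <- NULL
    while (i <= length(lines) && lines[i] != "" &&
           !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      if (grepl("^ID\\s*=", lines[i], ignore.case = TRUE))
        id <- sub("^ID\\s*=\\s*", "", lines[i], ignore.case = TRUE)
      i <- i + 1L
    }
    if (is.null(id)) id <- paste0("specimen_", length(curves) + 1L)
    curves[[length(curves) + 1L]] <- landmark_curve(id, xy)
  }
  curves
}

read_landmarks_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "point_index", "x", "y")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("CSV parse error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  if (!is.numeric(tab$x) || !is.numeric(tab$y))
    stop("CSV parse error in ", path, ": x and y must be numeric")
  ids <- unique(tab$specimen_id)
  lapply(ids, function(id) {
    rows <- tab[tab$specimen_id == id, , drop = FALSE]
    rows <- rows[order(rows$point_index), , drop = FALSE]
    landmark_curve(id, cbind(rows$x, rows$y))
  })
}

#' Write semi-landmark curves to the CSV dialect
#'
#' @param curves List of [landmark_curve] objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_landmarks <- function(curves, path) {
  rows <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(specimen_id = cv$specimen_id,
               point_index = seq_len(cv$n_points),
               x = cv$coords[, 1], y = cv$coords[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a curve to equidistant semi-landmarks
#'
#' Interpolates linearly along the input polyline so that the returned curve
#' has exactly `n` points at equal arc-length spacing. The endpoints are
#' preserved exactly. No smoothing is applied: smoothing would alter the
#' complexity scores computed downstream.
#'
#' @param curve A [landmark_curve] or a two-column coordinate matrix.
#' @param n Target number of semi-landmarks (>= 2). The conventional default
#'   for suture outlines is 500.
#' @return Object of the same kind as the input (curve or matrix) with `n`
#'   points.
#' @examples
#' resample_equidistant(cbind(c(0, 10), c(0, 0)), n = 5)
#' @export
resample_equidistant <- function(curve, n) {
  is_curve <- inherits(curve, "landmark_curve")
  xy <- if (is_curve) curve$coords else as.matrix(curve)
  if (n < 2) stop("n must be >= 2")
  seg <- sqrt(rowSums(diff(xy)^2))
  total <- sum(seg)
  if (total <= 0)
    stop("degenerate curve: total path length is zero",
         if (is_curve) paste0(" (specimen ", curve$specimen_id, ")") else "")
  s <- c(0, cumsum(seg))
  target <- seq(0, total, length.out = n)
  # approx() handles repeated arc-length values at zero-length segments
  new_x <- stats::approx(s, xy[, 1], xout = target, ties = "ordered")$y
  new_y <- stats::approx(s, xy[, 2], xout = target, ties = "ordered")$y
  out <- cbind(new_x, new_y)
  out[1, ] <- xy[1, ]
  out[n, ] <- xy[nrow(xy), ]
  colnames(out) <- c("x", "y")
  if (is_curve) landmark_curve(curve$specimen_id, out) else out
}

#' Write a complexity-score table to CSV
#'
#' Writes one row per specimen at full decimal precision so that the table
#' round-trips through [read_scores()] without loss.
#'
#' @param table Data frame with a `specimen_id` column plus numeric metric
#'   columns.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("score table must be a non-empty data frame")
  fmt <- table
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], function(v) sprintf("%.17g", v))
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a complexity-score table written by [write_scores()]
#'
#' @param path CSV file path.
#' @return Data frame with `specimen_id` as character and metric columns
#'   numeric.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
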