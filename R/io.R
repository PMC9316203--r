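# Readers and writers for the outline interchange formats the pipeline
# touches: long-format XY coordinate CSV, TPS outline records, and
# SHAPE-style Freeman chain-code (.chc) files.
#
# XY CSV dialect: comma-separated, header required
#   (specimen_id, point_index, x, y), decimal point.
# TPS dialect: OUTLINES=1 / POINTS=n blocks, "x y" coordinate lines,
#   ID=... closing each record; unknown keys are ignored with a warning.
# CHC dialect: one record per specimen,
#   "name x0 y0 n_codes code code ...", codes 0..7 (Freeman 8-direction,
#   0 = +x, counterclockwise), possibly wrapped over several lines.

#' Read outlines from a file
#'
#' @param path File path.
#' @param format One of `"xy_csv"`, `"tps"`, `"chc"`. Defaults from the
#'   file extension (`.csv`, `.tps`, `.chc`).
#' @return A list of [outline()] objects. Clockwise inputs are silently
#'   reversed to counterclockwise (recorded in provenance); coordinates
#'   are otherwise preserved exactly.
#' @export
read_outlines <- function(path, format = NULL) {
  format <- resolve_format(path, format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- switch(format,
                xy_csv = read_xy_csv(path),
                tps = read_tps(path),
                chc = read_chc(path))
  ids <- vapply(out, function(o) o$specimen_id, "")
  if (anyDuplicated(ids))
    stop("duplicate specimen_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  out
}

#' Write outlines to a file
#'
#' XY CSV and TPS round-trip coordinates losslessly (to 1e-9); chain-code
#' export quantizes coordinates to a grid (see `grid`) and is therefore
#' lossy, with Hausdorff error bounded by about one grid unit.
#'
#' @param outlines A list of [outline()] objects (or a single one).
#' @param path Output file path.
#' @param format One of `"xy_csv"`, `"tps"`, `"chc"`; defaults from the
#'   extension.
#' @param grid Chain-code grid spacing (length units per step). Default:
#'   1/1024 of the first outline's perimeter.
#' @return Invisibly, `path`.
#' @export
write_outlines <- function(outlines, path, format = NULL, grid = NULL) {
  format <- resolve_format(path, format)
  if (inherits(outlines, "outline")) outlines <- list(outlines)
  stopifnot(all(vapply(outlines, inherits, TRUE, "outline")))
  switch(format,
         xy_csv = write_xy_csv(outlines, path),
         tps = write_tps(outlines, path),
         chc = write_chc(outlines, path, grid = grid))
  invisible(path)
}

resolve_format <- function(path, format) {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "xy_csv", tps = "tps", chc = "chc",
                     stop("cannot infer format from extension of ", path,
                          call. = FALSE))
  }
  match.arg(format, c("xy_csv", "tps", "chc"))
}

## ---- XY CSV -------------------------------------------------------------

read_xy_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "point_index", "x", "y")
  if (!all(need %in% names(df)))
    stop(path, ": XY CSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  has_group <- "group" %in% names(df)
  ids <- unique(df$specimen_id)
  lapply(ids, function(id) {
    rows <- df[df$specimen_id == id, , drop = FALSE]
    rows <- rows[order(rows$point_index), , drop = FALSE]
    if (nrow(rows) < 3L)
      stop(path, ": specimen '", id, "' has fewer than 3 points (first at ",
           "data line ", which(df$specimen_id == id)[1L] + 1L, ")",
           call. = FALSE)
    if (anyDuplicated(rows$point_index))
      stop(path, ": specimen '", id, "' has duplicated point_index values",
           " (duplicate specimen record?)", call. = FALSE)
    outline(cbind(rows$x, rows$y), specimen_id = id,
            group = if (has_group) rows$group[1L] else NA_character_)
  })
}

write_xy_csv <- function(outlines, path) {
  dfs <- lapply(outlines, function(o) {
    data.frame(specimen_id = o$specimen_id,
               group = o$group,
               point_index = seq_len(nrow(o$points)),
               x = o$points[, 1], y = o$points[, 2])
  })
  df <- do.call(rbind, dfs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("specimen_id,group,point_index,x,y", con)
  writeLines(sprintf("%s,%s,%d,%.17g,%.17g",
                     df$specimen_id, df$group, df$point_index, df$x, df$y),
             con)
}

## ---- TPS ----------------------------------------------------------------

read_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  n_lines <- length(lines)
  while (i <= n_lines) {
    line <- trimws(lines[i])
    if (line == "") { i <- i + 1L; next }
    if (!grepl("^OUTLINES=", line, ignore.case = TRUE))
      stop(path, ", line ", i, ": expected OUTLINES= record start, got '",
           line, "'", call. = FALSE)
    n_out <- as.integer(sub("^OUTLINES=", "", line, ignore.case = TRUE))
    if (is.na(n_out) || n_out != 1L)
      stop(path, ", line ", i, ": only OUTLINES=1 records are supported",
           call. = FALSE)
    i <- i + 1L
    if (i > n_lines || !grepl("^POINTS=", trimws(lines[i]),
                              ignore.case = TRUE))
      stop(path, ", line ", i, ": expected POINTS=", call. = FALSE)
    npts <- as.integer(sub("^POINTS=", "", trimws(lines[i]),
                           ignore.case = TRUE))
    if (is.na(npts) || npts < 3L)
      stop(path, ", line ", i, ": invalid POINTS count", call. = FALSE)
    i <- i + 1L
    if (i + npts - 1L > n_lines)
      stop(path, ", line ", i, ": truncated coordinate block", call. = FALSE)
    coords <- matrix(NA_real_, npts, 2L)
    for (k in seq_len(npts)) {
      vals <- suppressWarnings(
        as.numeric(strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]))
      if (length(vals) != 2L || anyNA(vals))
        stop(path, ", line ", i, ": expected 'x y' coordinates",
             call. = FALSE)
      coords[k, ] <- vals
      i <- i + 1L
    }
    id <- sprintf("tps_%d", length(out) + 1L)
    # trailing keys until the next OUTLINES= or EOF
    while (i <= n_lines && !grepl("^OUTLINES=", trimws(lines[i]),
                                  ignore.case = TRUE)) {
      kv <- trimws(lines[i])
      if (kv != "") {
        if (grepl("^ID=", kv, ignore.case = TRUE)) {
          id <- sub("^ID=", "", kv, ignore.case = TRUE)
        } else if (grepl("=", kv, fixed = TRUE)) {
          warning(path, ", line ", i, ": ignoring unknown TPS key '",
                  sub("=.*$", "", kv), "'", call. = FALSE)
        } else {
          break
        }
      }
      i <- i + 1L
    }
    out[[length(out) + 1L]] <- outline(coords, specimen_id = id)
  }
  out
}

write_tps <- function(outlines, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (o in outlines) {
    writeLines(c("OUTLINES=1",
                 sprintf("POINTS=%d", nrow(o$points)),
                 sprintf("%.17g %.17g", o$points[, 1], o$points[, 2]),
                 sprintf("ID=%s", o$specimen_id)),
               con)
  }
}

## ---- Freeman chain codes ------------------------------------------------

freeman_steps <- rbind(c(1, 0), c(1, 1), c(0, 1), c(-1, 1),
                       c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))

#' Decode a Freeman chain code into grid coordinates
#'
#' @param codes Integer vector of 8-direction codes (0..7; 0 = +x,
#'   counterclockwise).
#' @param start Integer grid origin `c(x, y)`.
#' @return Matrix of grid points visited (closing point omitted).
#' @export
chain_decode <- function(codes, start = c(0, 0)) {
  codes <- as.integer(codes)
  if (any(codes < 0L | codes > 7L))
    stop("chain codes must be in 0..7", call. = FALSE)
  steps <- freeman_steps[codes + 1L, , drop = FALSE]
  disp <- colSums(steps)
  if (any(disp != 0L))
    stop("chain code is not closed (net displacement ", disp[1], ",",
         disp[2], ")", call. = FALSE)
  pts <- rbind(start, sweep(apply(steps, 2, cumsum), 2, -start, `-`))
  pts[-nrow(pts), , drop = FALSE]
}

# 8-connected grid path between two grid points (Bresenham-like;
# excludes the start point, includes the end point)
grid_path <- function(a, b) {
  d <- b - a
  n <- max(abs(d))
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  t <- seq_len(n) / n
  cbind(round(a[1] + t * d[1]), round(a[2] + t * d[2]))
}

# encode a polygon (real coordinates) as a chain code on a grid
chain_encode <- function(p, grid) {
  g <- round(p / grid)
  pts <- g[1L, , drop = FALSE]
  n <- nrow(g)
  for (i in seq_len(n)) {
    nxt <- g[if (i == n) 1L else i + 1L, ]
    seg <- grid_path(pts[nrow(pts), ], nxt)
    if (nrow(seg)) pts <- rbind(pts, seg)
  }
  pts <- pts[-nrow(pts), , drop = FALSE]   # drop closing duplicate
  d <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE]) - pts
  codes <- integer(nrow(d))
  for (k in seq_len(8L)) {
    hit <- d[, 1] == freeman_steps[k, 1] & d[, 2] == freeman_steps[k, 2]
    codes[hit] <- k - 1L
  }
  list(start = pts[1L, ], codes = codes)
}

read_chc <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE)
  out <- list()
  i <- 1L
  while (i <= length(toks)) {
    name <- toks[i]
    if (i + 3L > length(toks))
      stop(path, ": truncated chain-code record for '", name, "'",
           call. = FALSE)
    x0 <- as.numeric(toks[i + 1L]); y0 <- as.numeric(toks[i + 2L])
    nc <- as.integer(toks[i + 3L])
    if (anyNA(c(x0, y0, nc)) || nc < 4L)
      stop(path, ": malformed chain-code header for '", name, "'",
           call. = FALSE)
    if (i + 3L + nc > length(toks))
      stop(path, ": chain code for '", name, "' shorter than declared (",
           nc, " codes)", call. = FALSE)
    codes <- suppressWarnings(as.integer(toks[(i + 4L):(i + 3L + nc)]))
    if (anyNA(codes))
      stop(path, ": non-integer chain code for '", name, "'", call. = FALSE)
    pts <- chain_decode(codes, start = c(x0, y0))
    out[[length(out) + 1L]] <- outline(pts, specimen_id = name,
                                       provenance = "chain-code")
    i <- i + 4L + nc
  }
  out
}

write_chc <- function(outlines, path, grid = NULL) {
  if (is.null(grid)) grid <- perimeter(outlines[[1L]]$points) / 1024
  con <- file(path, "w")
  on.exit(close(con))
  for (o in outlines) {
    enc <- chain_encode(o$points, grid)
    writeLines(paste(c(o$specimen_id, enc$start[1], enc$start[2],
                       length(enc$codes), enc$codes), collapse = " "),
               con)
  }
  invisible(grid)
}
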