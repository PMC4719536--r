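#' Coverage grid for saturation analysis
#'
#' @param start,stop,step Coverage levels (x-fold). Defaults span
#'   200x-3000x in 100-fold increments, the grid used to find the
#'   assembler's saturation point.
#' @return Integer vector of coverage levels, class `coverage_grid`.
#' @export
coverage_grid <- function(start = 200, stop = 3000, step = 100) {
  if (start > stop) stop("grid start must be <= stop")
  if (step <= 0) stop("grid step must be positive")
  structure(seq(start, stop, by = step), class = "coverage_grid")
}

#' Plan the subsampling experiment
#'
#' One assembly job per (clone, coverage level). With 11 clones and
#' the default 200-3000x step-100 grid this yields 319 jobs.
#'
#' @param clones Number of clones, or a character vector of clone ids.
#' @param grid A [coverage_grid()] (or plain numeric vector of
#'   levels).
#' @return Data.frame `(clone, coverage)` ordered by clone then
#'   ascending coverage.
#' @export
plan_subsamples <- function(clones, grid = coverage_grid()) {
  if (length(grid) == 0) stop("empty coverage grid")
  if (is.numeric(clones) && length(clones) == 1) {
    if (clones < 1) stop("need at least one clone")
    clones <- sprintf("clone%02d", seq_len(clones))
  }
  out <- expand.grid(coverage = as.numeric(grid), clone = clones,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(match(out$clone, clones), out$coverage), c("clone", "coverage")]
  rownames(out) <- NULL
  out
}

#' Subsample read pairs with replacement to a target coverage
#'
#' Draws `ceiling(target_coverage * unit_length / (2 *
#' effective_read_length))` pairs uniformly with replacement. When
#' `trim_to` is set, reads (and qualities) are first truncated to that
#' many bases and the effective read length becomes `trim_to`,
#' emulating subsampling at a shorter read length.
#'
#' @param pairs Read-pair data.frame.
#' @param target_coverage Coverage to draw (x-fold).
#' @param unit_length Reference unit length (bp).
#' @param read_length Full read length of the input pairs.
#' @param trim_to Optional truncation length (bp), `<= read_length`.
#' @param seed Integer seed; the drawn multiset is deterministic.
#' @return A read-pair data.frame of the drawn pairs.
#' @export
subsample_pairs <- function(pairs, target_coverage, unit_length, read_length,
                            trim_to = NULL, seed = 1L) {
  if (nrow(pairs) == 0) stop("no pairs to subsample")
  if (target_coverage <= 0) stop("target_coverage must be positive")
  eff <- read_length
  if (!is.null(trim_to)) {
    if (trim_to > read_length) stop("trim_to exceeds the read length")
    if (trim_to < 1) stop("trim_to must be positive")
    eff <- trim_to
  }
  n <- ceiling(target_coverage * unit_length / (2 * eff))
  idx <- with_seed(seed, sample.int(nrow(pairs), n, replace = TRUE))
  out <- pairs[idx, , drop = FALSE]
  if (!is.null(trim_to)) {
    out$read1 <- substr(out$read1, 1L, trim_to)
    out$read2 <- substr(out$read2, 1L, trim_to)
    if (!is.null(out$quality1)) out$quality1 <- substr(out$quality1, 1L, trim_to)
    if (!is.null(out$quality2)) out$quality2 <- substr(out$quality2, 1L, trim_to)
  }
  rownames(out) <- NULL
  out
}

# One local weighted polynomial fit, returning the value at x0.
# Falls back to lower degree on a rank-deficient local system.
local_poly_fit <- function(dx, yw, wts, degree) {
  keep <- wts > 0
  for (deg in seq(degree, 0)) {
    if (sum(keep) < deg + 1) next
    X <- stats::poly(dx, degree = max(deg, 1), raw = TRUE, simple = TRUE)
    X <- cbind(1, X)[, seq_len(deg + 1), drop = FALSE]
    fit <- stats::lm.wfit(X, yw, wts)
    if (fit$rank == deg + 1) {
      return(list(value = fit$coefficients[1], degree = deg))
    }
  }
  # last resort: weighted mean
  list(value = sum(wts * yw) / sum(wts), degree = 0L)
}

#' Local polynomial (LOESS) smoothing with tricube weights
#'
#' At each input point `x0` a weighted polynomial of the requested
#' degree is fitted over the `ceiling(span * n)` nearest points, with
#' tricube weights `w = (1 - (d/dmax)^3)^3` where `d` is the distance
#' to `x0` and `dmax` the largest distance in the window; the smoothed
#' value is the local fit evaluated at `x0`. A singular local system
#' falls back to the next lower degree and is recorded in the
#' `fallback` attribute.
#'
#' @param x Strictly increasing predictor values.
#' @param y Response values.
#' @param span Fraction of points per local window, in (0, 1\].
#' @param degree Local polynomial degree: 0, 1 or 2.
#' @return Numeric vector of fitted values at each `x`, with attribute
#'   `fallback` (integer indices where the degree was reduced).
#' @export
loess_fit <- function(x, y, span = 0.75, degree = 2) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < degree + 1) stop("need at least degree + 1 points")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  if (!(degree %in% 0:2)) stop("degree must be 0, 1 or 2")
  q <- ceiling(span * n)
  if (q < degree + 1) {
    stop("local window (", q, " points) smaller than degree + 1")
  }
  fitted <- numeric(n)
  fallback <- integer(0)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    ord <- order(d, seq_len(n))
    win <- ord[seq_len(q)]
    dmax <- max(d[win])
    wts <- if (dmax == 0) rep(1, q) else (1 - pmin(d[win] / dmax, 1)^3)^3
    res <- local_poly_fit(x[win] - x[i], y[win], wts, degree)
    fitted[i] <- res$value
    if (res$degree < degree) fallback <- c(fallback, i)
  }
  if (length(fallback) > 0) {
    warning("singular local fit at ", length(fallback),
            " point(s); degree reduced there")
  }
  attr(fitted, "fallback") <- fallback
  fitted
}

#' Find the coverage plateau of a saturation curve
#'
#' Scans the fitted curve inside the analysis window (200x-1000x by
#' default, where assembly length is fitted) and returns the smallest
#' coverage whose smoothed assembly length reaches `(1 - epsilon)` of
#' the window maximum — the point where added coverage stops buying
#' assembly length.
#'
#' @param coverage Coverage levels (x-fold), increasing.
#' @param fitted Smoothed assembly lengths at those levels.
#' @param epsilon Plateau tolerance as a fraction of the maximum
#'   (default 1 %).
#' @param window Two-element numeric: coverage window analysed.
#' @return The plateau coverage (smallest level within `window` whose
#'   fitted length is `>= (1 - epsilon) * max`).
#' @export
find_plateau <- function(coverage, fitted, epsilon = 0.01,
                         window = c(200, 1000)) {
  if (length(coverage) != length(fitted)) stop("coverage and fitted lengths differ")
  sel <- which(!is.na(fitted) & coverage >= window[1] & coverage <= window[2])
  if (length(sel) < 3) stop("need fitted values on at least 3 grid points in the window")
  m <- max(fitted[sel])
  thr <- (1 - epsilon) * m
  hit <- sel[fitted[sel] >= thr]
  min(coverage[hit])
}

# Materialise an assembler callback from either an R function
# (pairs -> contig sequences or total length) or a shell command
# template with {r1} {r2} {out} placeholders.
resolve_assembler <- function(assembler) {
  if (is.function(assembler)) return(assembler)
  if (is.character(assembler) && length(assembler) == 1) {
    template <- assembler
    return(function(pairs) {
      td <- tempfile("asm")
      dir.create(td)
      on.exit(unlink(td, recursive = TRUE))
      r1 <- file.path(td, "r1.fastq")
      r2 <- file.path(td, "r2.fastq")
      out <- file.path(td, "contigs.fasta")
      write_paired_fastq(pairs, r1, r2)
      cmd <- gsub("{r1}", r1, template, fixed = TRUE)
      cmd <- gsub("{r2}", r2, cmd, fixed = TRUE)
      cmd <- gsub("{out}", out, cmd, fixed = TRUE)
      status <- system(cmd)
      if (status != 0) stop("assembler command failed (exit ", status, "): ", cmd)
      as.character(read_fasta(out))
    })
  }
  stop("assembler must be a function or a command template string")
}

#' Build a coverage-saturation curve for one clone
#'
#' For each level of the coverage grid, subsamples the clone's read
#' pairs with replacement, hands them to the (pluggable, external)
#' assembler, and records the total assembled length. The curve is
#' then smoothed with [loess_fit()] over the analysis window.
#'
#' @param pairs The clone's full read-pair set.
#' @param grid A [coverage_grid()].
#' @param unit_length Clone unit length (bp) used for the subsample
#'   size formula.
#' @param read_length Input read length (bp).
#' @param assembler An R function `pairs -> contig sequences (or total
#'   length)`, or a shell command template containing `{r1}`, `{r2}`,
#'   `{out}` placeholders that writes contigs FASTA to `{out}`.
#' @param trim_to Optional read truncation before assembly (bp).
#' @param span,degree LOESS parameters (defaults 0.75 and 2).
#' @param fit_window Coverage window over which the curve is fitted.
#' @param clone_id Label stored on the curve.
#' @param seed Integer seed; level `i` uses `seed + i`.
#' @return Object of class `coverage_curve`: list with `clone_id`,
#'   `points` (data.frame coverage/assembly_length), `fitted`
#'   (data.frame coverage/smoothed_length over the fit window), and
#'   `n_fit_points`.
#' @export
saturation_curve <- function(pairs, grid, unit_length, read_length,
                             assembler, trim_to = NULL,
                             span = 0.75, degree = 2,
                             fit_window = c(200, 1000),
                             clone_id = "clone", seed = 1L) {
  asm <- resolve_assembler(assembler)
  levels <- as.numeric(grid)
  lengths <- vapply(seq_along(levels), function(i) {
    sub <- subsample_pairs(pairs, levels[i], unit_length, read_length,
                           trim_to = trim_to, seed = seed + i)
    res <- asm(sub)
    if (is.character(res)) sum(nchar(res)) else as.numeric(res)
  }, numeric(1))
  points <- data.frame(coverage = levels, assembly_length = lengths)
  in_win <- levels >= fit_window[1] & levels <= fit_window[2]
  fitted <- NULL
  if (sum(in_win) >= degree + 1) {
    sm <- loess_fit(levels[in_win], lengths[in_win], span = span, degree = degree)
    fitted <- data.frame(coverage = levels[in_win], smoothed_length = as.numeric(sm))
  }
  structure(list(clone_id = clone_id, points = points, fitted = fitted,
                 n_fit_points = sum(in_win)),
            class = "coverage_curve")
}

#' Optimal coverage from a saturation curve
#'
#' @param curve A [saturation_curve()] object with fitted values.
#' @param epsilon Plateau tolerance (see [find_plateau()]).
#' @param window Analysis window (defaults to the curve's fitted
#'   range).
#' @return The plateau coverage.
#' @export
optimal_coverage <- function(curve, epsilon = 0.01, window = NULL) {
  if (is.null(curve$fitted)) stop("curve has no fitted values")
  if (is.null(window)) window <- range(curve$fitted$coverage)
  find_plateau(curve$fitted$coverage, curve$fitted$smoothed_length,
               epsilon = epsilon, window = window)
}

#' Write a coverage curve as TSV
#'
#' @param curve A `coverage_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_curve <- function(curve, path) {
  pts <- curve$points
  pts$smoothed_length <- NA_real_
  if (!is.null(curve$fitted)) {
    m <- match(curve$fitted$coverage, pts$coverage)
    pts$smoothed_length[m] <- curve$fitted$smoothed_length
  }
  pts <- cbind(clone = curve$clone_id, pts)
  utils::write.table(pts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
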