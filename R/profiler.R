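# Sequence records and sliding-window hydropathy profiles.

#' Create a protein sequence record
#'
#' @param id Identifier (e.g. a UniProt accession).
#' @param residues One-letter amino-acid string; upper-cased on input.
#'   A single terminal '*' (stop) is stripped.
#' @param species,protein Optional labels used in comparison tables.
#' @param region Optional 1-based inclusive \code{c(start, end)} restricting
#'   analysis to a subsequence, typically a motor domain (~350 aa for
#'   kinesins).  Default: the whole sequence.
#' @return An object of class \code{seq_record}.
#' @export
seq_record <- function(id, residues, species = "", protein = "",
                       region = NULL) {
  residues <- toupper(gsub("[ \t\r\n]", "", residues))
  residues <- sub("\\*$", "", residues)
  n <- nchar(residues)
  if (n == 0L) stop("empty sequence for record '", id, "'", call. = FALSE)
  if (!is.null(region)) {
    region <- as.integer(region)
    if (length(region) != 2L || region[1] < 1L || region[2] > n ||
        region[1] > region[2])
      stop("region must be 1-based c(start, end) within [1, ", n, "]",
           call. = FALSE)
  }
  structure(list(id = as.character(id), species = as.character(species),
                 protein = as.character(protein), residues = residues,
                 region = region),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat("<seq_record> ", x$id,
      if (nzchar(x$protein)) paste0(" protein=", x$protein),
      if (nzchar(x$species)) paste0(" species=", x$species),
      "  length=", nchar(x$residues),
      if (!is.null(x$region)) sprintf("  region=%d:%d",
                                      x$region[1], x$region[2]),
      "\n", sep = "")
  invisible(x)
}

region_of <- function(record) {
  if (is.null(record$region)) c(1L, nchar(record$residues))
  else record$region
}

as_seq_record <- function(x) {
  if (inherits(x, "seq_record")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(seq_record(id = "seq", residues = x))
  stop("expected a seq_record or a single residue string", call. = FALSE)
}

#' Compute a sliding-window hydropathy profile
#'
#' The profile value at center position \eqn{i} is the arithmetic mean of
#' the scale values over positions \eqn{i - (W-1)/2, \ldots, i + (W-1)/2}.
#' Windows are truncated at the region edges: no value is emitted for a
#' center whose window would overrun the analyzed region, so a region of
#' length \eqn{n} yields \eqn{n - W + 1} values.  Positions are reported as
#' 1-based indices into the full original sequence even when a region is
#' set, so peaks can be compared across species on a common axis.
#'
#' @param record A \code{seq_record} (or a bare residue string).
#' @param scale A \code{hydropathy_scale}, or a scale name (\code{"MZ"},
#'   \code{"KD"}).  Default MZ.
#' @param window Odd sliding-window width \eqn{W \ge 1} (default 9, the
#'   optimal width for human kinesin motor domains).
#' @param na_action What to do with residues lacking a scale value
#'   (\code{B}, \code{Z}, \code{X}, \code{U}, \code{O}): \code{"error"}
#'   (default) or \code{"impute"} the scale mean.
#' @return An object of class \code{hydro_profile}: list with
#'   \code{sequence_id}, \code{scale_name}, \code{window},
#'   \code{positions} (1-based window centers) and \code{values}.
#' @examples
#' p <- compute_profile("MKTAYIAKQRQISFVKSHFSRQ", scale = "KD", window = 9)
#' as.data.frame(p)
#' @export
compute_profile <- function(record, scale = "MZ", window = 9,
                            na_action = c("error", "impute")) {
  record <- as_seq_record(record)
  if (is.character(scale)) scale <- load_scale(scale)
  stopifnot(inherits(scale, "hydropathy_scale"))
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L)
    stop("window must be a positive integer", call. = FALSE)
  if (window %% 2L == 0L)
    stop("window must be odd (W = 2N + 1); got ", window, call. = FALSE)
  reg <- region_of(record)
  sub <- substr(record$residues, reg[1], reg[2])
  n <- nchar(sub)
  if (window > n)
    stop("window (", window, ") exceeds region length (", n, ")",
         call. = FALSE)
  v <- scale_values_for(sub, scale, match.arg(na_action))
  h <- (window - 1L) %/% 2L
  vals <- as.numeric(stats::filter(v, rep(1 / window, window), sides = 2))
  centers <- seq.int(1L + h, n - h)
  structure(
    list(sequence_id = record$id,
         scale_name = scale$name,
         hydrophobic_is_max = scale$hydrophobic_is_max,
         window = window,
         positions = centers + reg[1] - 1L,
         values = vals[centers]),
    class = "hydro_profile")
}

#' @export
print.hydro_profile <- function(x, ...) {
  cat("<hydro_profile> ", x$sequence_id, "  scale=", x$scale_name,
      "  W=", x$window, "  ", length(x$values), " values over positions ",
      x$positions[1], "..", x$positions[length(x$positions)], "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.hydro_profile <- function(x, ...) {
  data.frame(position = x$positions, value = x$values)
}

#' @export
plot.hydro_profile <- function(x, mark_peaks = TRUE, k = 5,
                               min_separation = 10, ...) {
  graphics::plot(x$positions, x$values, type = "l",
                 xlab = "sequence position",
                 ylab = sprintf("Psi(aa, W=%d)  [%s]", x$window,
                                x$scale_name), ...)
  if (mark_peaks && length(x$values) >= 3) {
    ex <- find_extrema(x, min_separation = min_separation)
    pk <- ex[ex$kind == "peak", , drop = FALSE]
    if (nrow(pk)) {
      pk <- pk[order(-pk$value, pk$position), , drop = FALSE]
      top <- utils::head(pk, k)
      graphics::points(top$position, top$value, pch = 19)
      graphics::text(top$position, top$value,
                     labels = rank(-top$value, ties.method = "first"),
                     pos = 3, cex = 0.8)
    }
  }
  invisible(x)
}

#' Sweep the smoothing window and locate the optimal width W*
#'
#' Computes the profile and the k-peak level deviation statistic for each
#' window width, and reports the width minimizing the statistic (the most
#' level peak set) as \code{w_star}, with ties broken toward the smaller
#' window.  This operationalizes as a minimizer what is usually read off
#' graphs by eye; widths where the profile yields fewer than two peaks get
#' \code{NA} and are excluded from the minimization.  If no window yields
#' a statistic, \code{w_star} is \code{NA}.
#'
#' @inheritParams compute_profile
#' @param windows Odd window widths to try (default \code{seq(7, 21, 2)}).
#' @param k Number of highest peaks scored (default 5).
#' @param definition Deviation definition, \code{"mad"} (mean absolute
#'   deviation, default) or \code{"sd"}.
#' @param min_separation Minimum residue separation between retained peaks
#'   (default 10).
#' @return Object of class \code{window_sweep}: list with \code{table}
#'   (data frame window/deviation/n_peaks/note), \code{profiles},
#'   \code{stats} and \code{w_star}.
#' @export
window_sweep <- function(record, scale = "MZ", windows = seq(7, 21, 2),
                         k = 5, definition = c("mad", "sd"),
                         min_separation = 10,
                         na_action = c("error", "impute")) {
  record <- as_seq_record(record)
  if (is.character(scale)) scale <- load_scale(scale)
  definition <- match.arg(definition)
  na_action <- match.arg(na_action)
  windows <- as.integer(windows)
  if (length(windows) == 0L) stop("empty window list", call. = FALSE)
  if (any(windows %% 2L == 0L))
    stop("all windows must be odd", call. = FALSE)
  profiles <- list(); stats_l <- list()
  dev <- rep(NA_real_, length(windows))
  npk <- integer(length(windows))
  note <- character(length(windows))
  for (j in seq_along(windows)) {
    w <- windows[j]
    p <- compute_profile(record, scale, w, na_action)
    profiles[[as.character(w)]] <- p
    st <- tryCatch({
      pk <- top_k_peaks(find_extrema(p, min_separation), k = k)
      level_deviation(pk, definition)
    }, error = function(e) e)
    if (inherits(st, "error")) {
      note[j] <- conditionMessage(st)
      stats_l[as.character(w)] <- list(NULL)
    } else {
      stats_l[[as.character(w)]] <- st
      dev[j] <- st$deviation
      npk[j] <- st$n_peaks
      if (st$n_peaks < k) note[j] <- "short peak set"
    }
  }
  w_star <- if (all(is.na(dev))) NA_integer_ else {
    ok <- which(!is.na(dev))
    ok <- ok[order(dev[ok], windows[ok])]   # ties -> smaller window
    windows[ok[1]]
  }
  structure(
    list(table = data.frame(window = windows, deviation = dev,
                            n_peaks = npk, note = note),
         profiles = profiles, stats = stats_l, w_star = w_star,
         k = k, definition = definition, scale_name = profiles[[1]]$scale_name),
    class = "window_sweep")
}

#' @export
print.window_sweep <- function(x, ...) {
  cat("Window sweep (", x$scale_name, " scale, k = ", x$k, ", ",
      x$definition, "):\n", sep = "")
  print(transform(x$table, deviation = round(deviation, 4)),
        row.names = FALSE)
  if (is.na(x$w_star))
    cat("No window produced a scoreable peak set; W* undefined.\n")
  else
    cat("W* =", x$w_star, "(minimum deviation)\n")
  invisible(x)
}

#' @export
plot.window_sweep <- function(x, ...) {
  graphics::plot(x$table$window, x$table$deviation, type = "b",
                 xlab = "window width W", ylab = "level deviation", ...)
  if (!is.na(x$w_star))
    graphics::abline(v = x$w_star, lty = 3)
  invisible(x)
}
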