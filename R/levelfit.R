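# The central fit: sequence -> profile -> peaks -> level statistic.

#' Fit the level-set synchronization statistic to a protein sequence
#'
#' The one-call pipeline: computes the sliding-window hydropathy profile of
#' the (region of the) sequence, finds interior extrema, selects the
#' \code{k} highest hydrophobic peaks (or lowest hydrophilic valleys) and
#' scores how level ("synchronized") they are by their deviation from the
#' common mean.  A small deviation means the peak heights form a level set,
#' which in kinesin motor domains is read as an evolutionary refinement of
#' multi-domain hydrodynamics; a large deviation means practically no
#' level set.
#'
#' Defaults reproduce the standard analysis settings for kinesin motor
#' domains: MZ scale, W = 9, k = 5, mean absolute deviation,
#' minimum peak separation 10 residues.
#'
#' @inheritParams compute_profile
#' @inheritParams window_sweep
#' @param polarity \code{"peaks"} (hydrophobic maxima, default) or
#'   \code{"valleys"} (hydrophilic minima).
#' @return An object of class \code{levelfit} with components
#'   \code{record}, \code{profile} (\code{hydro_profile}), \code{extrema},
#'   \code{peaks} (\code{peak_set}), \code{stat} (\code{level_stat}) and
#'   \code{call}.  Methods: \code{print}, \code{summary}, \code{coef}
#'   (mean level and deviation), \code{residuals} (peak heights minus the
#'   mean level), \code{plot} (profile with the scored peaks numbered) and
#'   \code{simulate} (synthetic sequences with the fitted level and
#'   spread; see [simulate.levelfit()]).
#' @examples
#' set.seed(1)
#' rec <- generate_sequence(synthetic_spec(level_spread = 0.5, seed = 1))$record
#' fit <- levelfit(rec, scale = "KD")
#' fit
#' coef(fit)
#' @export
levelfit <- function(record, scale = "MZ", window = 9, k = 5,
                     definition = c("mad", "sd"),
                     min_separation = 10,
                     polarity = c("peaks", "valleys"),
                     na_action = c("error", "impute")) {
  record <- as_seq_record(record)
  if (is.character(scale)) scale <- load_scale(scale)
  definition <- match.arg(definition)
  polarity <- match.arg(polarity)
  profile <- compute_profile(record, scale, window, match.arg(na_action))
  extrema <- find_extrema(profile, min_separation)
  peaks <- top_k_peaks(extrema, k = k, polarity = polarity)
  stat <- level_deviation(peaks, definition)
  fit <- structure(
    list(record = record, scale = scale, profile = profile,
         extrema = extrema, peaks = peaks, stat = stat,
         params = list(window = window, k = k, definition = definition,
                       min_separation = min_separation,
                       polarity = polarity),
         call = match.call()),
    class = "levelfit")
  if (isTRUE(getOption("hydrolevels.verbose")))
    message(run_log_line(fit))
  fit
}

#' @export
print.levelfit <- function(x, ...) {
  cat("Level-set fit: ", x$record$id,
      if (nzchar(x$record$species)) paste0(" (", x$record$species, ")"),
      "\n", sep = "")
  cat(sprintf("  scale %s, W = %d, k = %d, %s, min_separation = %d, %s\n",
              x$scale$name, x$params$window, x$params$k,
              x$params$definition, x$params$min_separation,
              x$params$polarity))
  cat(sprintf("  mean level %.4f, deviation %.4f over %d %s%s\n",
              x$stat$mean_level, x$stat$deviation, x$stat$n_peaks,
              x$params$polarity,
              if (x$stat$short) " [short set]" else ""))
  invisible(x)
}

#' @export
summary.levelfit <- function(object, ...) {
  print(object)
  cat("Scored extrema:\n")
  print(transform(object$peaks$peaks, value = round(value, 4)),
        row.names = FALSE)
  mem <- level_members(object$peaks)
  cat(sprintf("Level-set members within epsilon = %.4f: %d of %d\n",
              mem$epsilon, mem$count, object$stat$n_peaks))
  invisible(list(stat = object$stat, peaks = object$peaks$peaks,
                 members = mem))
}

#' @export
coef.levelfit <- function(object, ...) {
  c(mean_level = object$stat$mean_level,
    deviation = object$stat$deviation)
}

#' @export
residuals.levelfit <- function(object, ...) {
  r <- object$peaks$peaks$value - object$stat$mean_level
  names(r) <- object$peaks$peaks$position
  r
}

#' @export
plot.levelfit <- function(x, ...) {
  plot(x$profile, mark_peaks = FALSE, ...)
  graphics::points(x$peaks$peaks$position, x$peaks$peaks$value, pch = 19)
  graphics::text(x$peaks$peaks$position, x$peaks$peaks$value,
                 labels = seq_len(nrow(x$peaks$peaks)), pos = 3, cex = 0.8)
  graphics::abline(h = x$stat$mean_level, lty = 3)
  invisible(x)
}

#' Simulate sequences matching a fitted level set
#'
#' Draws synthetic sequences whose planted peak level and spread equal the
#' fitted \code{mean_level} and \code{deviation}, on the same scale and
#' with the same k and window geometry, so the fit can be compared against
#' sequences with known ground truth.
#'
#' @param object A \code{levelfit}.
#' @param nsim Number of sequences.
#' @param seed Integer seed (passed to the generator; \code{NULL} leaves
#'   the RNG state alone).
#' @param ... Overrides forwarded to [synthetic_spec()].
#' @return List of \code{nsim} elements, each a list with \code{record}
#'   and \code{truth} as returned by [generate_sequence()].
#' @export
simulate.levelfit <- function(object, nsim = 1, seed = NULL, ...) {
  n <- nchar(object$record$residues)
  args0 <- list(length = max(n, 60L),
                k = object$params$k,
                motif_width = object$params$window,
                target_level = object$stat$mean_level,
                level_spread = object$stat$deviation,
                scale_name = object$scale$name,
                min_spacing = object$params$min_separation * 3L)
  dots <- list(...)
  args0[names(dots)] <- dots
  lapply(seq_len(nsim), function(i) {
    args0$seed <- if (is.null(seed)) NULL else seed + i - 1L
    generate_sequence(do.call(synthetic_spec, args0))
  })
}
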