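# Extremum detection, k-highest-peak selection, and the level-set
# synchronization statistic.

profile_values <- function(profile) {
  if (inherits(profile, "hydro_profile"))
    list(positions = profile$positions, values = profile$values)
  else if (is.numeric(profile))
    list(positions = seq_along(profile), values = as.numeric(profile))
  else stop("expected a hydro_profile or a numeric vector", call. = FALSE)
}

# Interior strict extrema with plateau reduction: a maximal run of equal
# values that is strictly above (below) both flanking values is a peak
# (valley) at its central index, ties toward the smaller index.  Runs
# touching either end of the profile are not interior and are dropped.
raw_extrema <- function(values) {
  r <- rle(values)
  m <- length(r$values)
  if (m < 3L) return(list(idx = integer(0), kind = character(0)))
  v <- r$values
  j <- 2:(m - 1L)
  is_peak <- v[j] > v[j - 1L] & v[j] > v[j + 1L]
  is_valley <- v[j] < v[j - 1L] & v[j] < v[j + 1L]
  sel <- j[is_peak | is_valley]
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- starts[sel] + (r$lengths[sel] - 1L) %/% 2L
  kind <- c("valley", "peak")[(v[sel] > v[sel - 1L]) + 1L]
  list(idx = idx, kind = kind)
}

# Enforce a minimum position distance within one kind: visit extrema from
# most extreme value down (ties toward smaller position), keep an extremum
# only if no already-kept one lies closer than min_separation.
thin_extrema <- function(positions, values, min_separation, decreasing) {
  if (length(positions) <= 1L || min_separation <= 1) return(seq_along(positions))
  ord <- order(if (decreasing) -values else values, positions)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) ||
        all(abs(positions[kept] - positions[i]) >= min_separation))
      kept <- c(kept, i)
  }
  sort(kept)
}

#' Find interior extrema of a hydropathy profile
#'
#' Interior local maxima (peaks) and minima (valleys): strictly greater or
#' less than both neighbors, with plateaus reduced to their central point.
#' Among peaks closer together than \code{min_separation} residues only the
#' higher survives (applied iteratively, highest first); likewise for
#' valleys, lowest first.
#'
#' @param profile A \code{hydro_profile}, or a bare numeric vector (then
#'   positions are its indices).
#' @param min_separation Minimum residue distance between retained extrema
#'   of the same kind (default 10, suited to ~350-residue motor domains
#'   smoothed with W = 9; set to 1 to disable thinning).
#' @return A data frame (class \code{extrema}) with columns
#'   \code{position}, \code{value}, \code{kind} ("peak"/"valley"), ordered
#'   by position.
#' @examples
#' find_extrema(c(1, 3, 2, 4, 2, 5, 1), min_separation = 1)
#' @export
find_extrema <- function(profile, min_separation = 10) {
  pv <- profile_values(profile)
  if (length(pv$values) < 3L)
    stop("profile must have at least 3 values", call. = FALSE)
  re <- raw_extrema(pv$values)
  position <- pv$positions[re$idx]
  value <- pv$values[re$idx]
  kind <- re$kind
  if (min_separation > 1 && length(position) > 1L) {
    keep <- logical(length(position))
    for (kd in c("peak", "valley")) {
      sel <- which(kind == kd)
      if (length(sel)) {
        ki <- thin_extrema(position[sel], value[sel],
                           min_separation, decreasing = (kd == "peak"))
        keep[sel[ki]] <- TRUE
      }
    }
    position <- position[keep]; value <- value[keep]; kind <- kind[keep]
  }
  # raw extrema come out position-ordered already
  structure(list(position = position, value = value, kind = kind),
            class = c("extrema", "data.frame"),
            row.names = if (length(position)) seq_along(position)
                        else integer(0))
}

#' Select the k highest hydrophobic peaks
#'
#' Takes the \code{k} largest-valued peaks from an extrema table; ties at
#' the cutoff are broken toward the smaller position.  If fewer than
#' \code{k} peaks exist, all are returned and the \code{short} flag is set.
#' With \code{polarity = "valleys"} the same machinery selects the k lowest
#' hydrophilic minima instead.
#'
#' @param extrema An \code{extrema} data frame from [find_extrema()].
#' @param k Number of peaks requested (default 5, \eqn{k \ge 2}).
#' @param polarity \code{"peaks"} (hydrophobic maxima, default) or
#'   \code{"valleys"} (hydrophilic minima).
#' @return An object of class \code{peak_set}: list with \code{peaks}
#'   (data frame position/value ordered by descending extremity), \code{k},
#'   \code{polarity} and logical \code{short}.
#' @export
top_k_peaks <- function(extrema, k = 5, polarity = c("peaks", "valleys")) {
  polarity <- match.arg(polarity)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  kd <- if (polarity == "peaks") "peak" else "valley"
  px <- extrema[extrema$kind == kd, , drop = FALSE]
  if (nrow(px) == 0L)
    stop("no ", kd, "s found: practically an empty level set", call. = FALSE)
  ord <- order(if (polarity == "peaks") -px$value else px$value,
               px$position)
  px <- px[ord, c("position", "value"), drop = FALSE]
  short <- nrow(px) < k
  px <- utils::head(px, k)
  rownames(px) <- NULL
  structure(list(peaks = px, k = as.integer(k), polarity = polarity,
                 short = short),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set> ", nrow(x$peaks), " of k = ", x$k, " ",
      x$polarity, if (x$short) "  [short set]", "\n", sep = "")
  print(transform(x$peaks, value = round(value, 4)), row.names = FALSE)
  invisible(x)
}

#' Level-set deviation of a peak set
#'
#' The synchronization score: \code{mean_level} is the arithmetic mean of
#' the peak values and \code{deviation} their mean absolute deviation about
#' it (\code{definition = "mad"}, default) or their sample standard
#' deviation (\code{"sd"}).  A perfectly level (synchronized) set scores 0;
#' smaller is more level.  The statistic is affine-equivariant: rescaling
#' the underlying hydropathy scale by slope \eqn{a} multiplies it by
#' \eqn{|a|}, so it is only comparable between runs on the same scale.
#'
#' @param peaks A \code{peak_set} with at least 2 peaks.
#' @param definition \code{"mad"} or \code{"sd"}.
#' @return Object of class \code{level_stat}: list with \code{mean_level},
#'   \code{deviation}, \code{definition}, \code{n_peaks}, \code{short}.
#' @examples
#' ex <- find_extrema(c(0, 1, 0, 2, 0, 3, 0, 4, 0, 5, 0), min_separation = 1)
#' level_deviation(top_k_peaks(ex, k = 5))        # mad of 1..5 = 1.2
#' level_deviation(top_k_peaks(ex, k = 5), "sd")  # sd of 1..5 ~ 1.5811
#' @export
level_deviation <- function(peaks, definition = c("mad", "sd")) {
  stopifnot(inherits(peaks, "peak_set"))
  definition <- match.arg(definition)
  v <- peaks$peaks$value
  if (length(v) < 2L)
    stop("need at least 2 peaks to measure a level deviation", call. = FALSE)
  m <- mean(v)
  d <- if (definition == "mad") mean(abs(v - m)) else stats::sd(v)
  structure(list(mean_level = m, deviation = d, definition = definition,
                 n_peaks = length(v), short = peaks$short),
            class = "level_stat")
}

#' @export
print.level_stat <- function(x, ...) {
  cat(sprintf("Level statistic (%s, %d peaks%s): mean level %.4f, deviation %.4f\n",
              x$definition, x$n_peaks, if (x$short) ", short set" else "",
              x$mean_level, x$deviation))
  invisible(x)
}

#' Members of the level set within a tolerance band
#'
#' Finds the largest subset of peaks whose values all lie within
#' \code{epsilon} of the subset mean (a band of total width
#' \eqn{2\epsilon}).  Because any optimal subset is contiguous in value
#' order, the exact answer is found by scanning value-sorted windows.
#'
#' @param peaks A \code{peak_set}.
#' @param epsilon Positive half-width of the tolerance band, in scale
#'   units.  Default: the peak set's own mean absolute deviation
#'   (self-scaling).
#' @return List with \code{count} and \code{members} (data frame of the
#'   member peaks, ordered by position).
#' @export
level_members <- function(peaks, epsilon = NULL) {
  stopifnot(inherits(peaks, "peak_set"))
  v <- peaks$peaks$value
  if (is.null(epsilon)) {
    if (length(v) < 2L)
      stop("default epsilon needs >= 2 peaks; give epsilon explicitly",
           call. = FALSE)
    epsilon <- mean(abs(v - mean(v)))
    # a perfectly level set has mad 0; any positive band keeps all members
    if (epsilon == 0) epsilon <- .Machine$double.eps^0.5
  }
  if (!is.finite(epsilon) && !is.infinite(epsilon))
    stop("epsilon must be a positive number", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  ord <- order(v)
  sv <- v[ord]
  n <- length(sv)
  best_i <- 1L; best_len <- 1L
  for (i in seq_len(n)) for (j in i:n) {
    m <- mean(sv[i:j])
    if (sv[j] - m <= epsilon && m - sv[i] <= epsilon) {
      if (j - i + 1L > best_len) { best_len <- j - i + 1L; best_i <- i }
    }
  }
  sel <- ord[best_i:(best_i + best_len - 1L)]
  members <- peaks$peaks[sort(sel), , drop = FALSE]
  members <- members[order(members$position), , drop = FALSE]
  rownames(members) <- NULL
  list(count = best_len, members = members, epsilon = epsilon)
}

#' Match peaks between two profiles by position
#'
#' Greedy nearest-position matching of peaks in profile \code{a} to peaks
#' in \code{b}: repeatedly pair the globally closest unmatched pair with
#' position offset at most \code{max_shift} (ties toward the smaller
#' position in \code{a}).  Supports numbered-peak comparisons between
#' species in the style of published profile overlays.
#'
#' @param a,b \code{hydro_profile}s computed with the same window and scale.
#' @param max_shift Maximum residue offset allowed for a match.
#' @param min_separation Passed to [find_extrema()].
#' @return Data frame with columns \code{position_a}, \code{value_a},
#'   \code{position_b}, \code{value_b} (NA where unmatched), one row per
#'   peak of \code{a}, plus rows with NA a-columns for unmatched b-peaks.
#' @export
match_peaks <- function(a, b, max_shift = 10, min_separation = 10) {
  stopifnot(inherits(a, "hydro_profile"), inherits(b, "hydro_profile"))
  if (a$window != b$window || a$scale_name != b$scale_name)
    stop("profiles must share window and scale (got W = ", a$window, "/",
         b$window, ", scales ", a$scale_name, "/", b$scale_name, ")",
         call. = FALSE)
  pa <- find_extrema(a, min_separation); pa <- pa[pa$kind == "peak", ]
  pb <- find_extrema(b, min_separation); pb <- pb[pb$kind == "peak", ]
  na_ <- nrow(pa); nb <- nrow(pb)
  match_b <- rep(NA_integer_, na_)
  if (na_ && nb) {
    d <- abs(outer(pa$position, pb$position, "-"))
    d[d > max_shift] <- NA
    free_a <- rep(TRUE, na_); free_b <- rep(TRUE, nb)
    repeat {
      dd <- d
      dd[!free_a, ] <- NA; dd[, !free_b] <- NA
      if (all(is.na(dd))) break
      # smallest distance; ties toward smaller a-position then b-position
      cand <- which(dd == min(dd, na.rm = TRUE), arr.ind = TRUE)
      cand <- cand[order(pa$position[cand[, 1]], pb$position[cand[, 2]]), ,
                   drop = FALSE]
      i <- cand[1, 1]; j <- cand[1, 2]
      match_b[i] <- j
      free_a[i] <- FALSE; free_b[j] <- FALSE
    }
  }
  out <- data.frame(position_a = pa$position, value_a = pa$value,
                    position_b = pb$position[match_b],
                    value_b = pb$value[match_b])
  un_b <- setdiff(seq_len(nb), match_b[!is.na(match_b)])
  if (length(un_b))
    out <- rbind(out, data.frame(position_a = NA_integer_,
                                 value_a = NA_real_,
                                 position_b = pb$position[un_b],
                                 value_b = pb$value[un_b]))
  rownames(out) <- NULL
  out
}

#' Compare the level statistic across species
#'
#' Runs the full pipeline (profile, extrema, k highest peaks, level
#' deviation) on each record with shared parameters and ranks species by
#' ascending deviation: the smallest deviation is the most level
#' (synchronized) peak set.  Records that fail (e.g. too few peaks) appear
#' with a status note and an NA deviation, ranked last.
#'
#' @param records List of \code{seq_record}s (each may carry its own
#'   region), or a single record.
#' @inheritParams window_sweep
#' @param window Single odd window width (default 9).
#' @return Object of class \code{species_comparison}: a data frame with
#'   columns \code{species}, \code{id}, \code{deviation}, \code{mean_level},
#'   \code{n_peaks}, \code{window}, \code{scale}, \code{rank}, \code{note},
#'   ordered by rank.
#' @export
compare_species <- function(records, scale = "MZ", window = 9, k = 5,
                            definition = c("mad", "sd"),
                            min_separation = 10,
                            na_action = c("error", "impute")) {
  if (inherits(records, "seq_record")) records <- list(records)
  if (!length(records)) stop("no records supplied", call. = FALSE)
  if (is.character(scale)) scale <- load_scale(scale)
  definition <- match.arg(definition)
  na_action <- match.arg(na_action)
  rows <- lapply(records, function(rec) {
    rec <- as_seq_record(rec)
    label <- if (nzchar(rec$species)) rec$species else rec$id
    res <- tryCatch({
      f <- levelfit(rec, scale = scale, window = window, k = k,
                    definition = definition,
                    min_separation = min_separation,
                    na_action = na_action)
      data.frame(species = label, id = rec$id,
                 deviation = f$stat$deviation,
                 mean_level = f$stat$mean_level,
                 n_peaks = f$stat$n_peaks,
                 window = window, scale = scale$name,
                 note = if (f$stat$short) "short peak set" else "",
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(species = label, id = rec$id, deviation = NA_real_,
                 mean_level = NA_real_, n_peaks = 0L, window = window,
                 scale = scale$name, note = conditionMessage(e),
                 stringsAsFactors = FALSE))
    res
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$deviation, tab$species, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- ifelse(is.na(tab$deviation), NA_integer_,
                     seq_len(nrow(tab)))
  rownames(tab) <- NULL
  tab <- tab[, c("rank", "species", "id", "deviation", "mean_level",
                 "n_peaks", "window", "scale", "note")]
  class(tab) <- c("species_comparison", "data.frame")
  tab
}

#' @export
print.species_comparison <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  y$deviation <- round(y$deviation, digits)
  y$mean_level <- round(y$mean_level, digits)
  cat("Level-set deviation ranking (ascending; smallest = most level):\n")
  print(y, row.names = FALSE)
  invisible(x)
}
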