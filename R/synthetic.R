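# Planted-peak sequence generator: synthetic sequences with known level-set
# ground truth for end-to-end validation of the pipeline.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Specify a planted-peak synthetic sequence
#'
#' Parameters of the generator used by [generate_sequence()].  The
#' generated sequence has a stochastic hydrophilic background plus \code{k}
#' hydrophobic motifs whose windowed profile means sit at heights drawn
#' from Normal(\code{target_level}, \code{level_spread}^2): with
#' \code{level_spread = 0} the planted peaks form a perfect level set (up
#' to residue quantization), and increasing the spread degrades the
#' synchronization.  Levels and spreads are in the units of the chosen
#' scale.
#'
#' @param length Sequence length in residues (default 360, a kinesin
#'   motor-domain-sized sequence).
#' @param k Number of planted peaks (default 5).
#' @param motif_width Width of each planted motif in residues; should be at
#'   least the analysis window (default 9).
#' @param target_level Common peak height in scale units (default 3 on the
#'   default KD scale; must lie within the scale's attainable range of
#'   window means).
#' @param level_spread Standard deviation sigma of the planted heights, in
#'   scale units (default 0: a perfect level set).
#' @param background_level Target mean of the background, in scale units
#'   (default -1).
#' @param min_spacing Minimum distance between motif centers (default 40).
#' @param seed Integer seed for reproducibility, or \code{NULL}.
#' @param scale_name Scale the levels refer to (default \code{"KD"}, whose
#'   familiar [-4.5, 4.5] units make levels and spreads easy to read).
#' @return A \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(length = 360, k = 5, motif_width = 9,
                           target_level = 3, level_spread = 0,
                           background_level = -1, min_spacing = 40,
                           seed = NULL, scale_name = "KD") {
  length <- as.integer(length); k <- as.integer(k)
  motif_width <- as.integer(motif_width)
  min_spacing <- as.integer(min_spacing)
  if (motif_width < 1L || motif_width %% 2L == 0L)
    stop("motif_width must be odd and positive", call. = FALSE)
  if (level_spread < 0) stop("level_spread must be >= 0", call. = FALSE)
  if (k < 0L) stop("k must be >= 0", call. = FALSE)
  if (k * (motif_width + min_spacing) > length)
    stop("infeasible packing: k * (motif_width + min_spacing) = ",
         k * (motif_width + min_spacing), " exceeds length ", length,
         call. = FALSE)
  structure(list(length = length, k = k, motif_width = motif_width,
                 target_level = target_level, level_spread = level_spread,
                 background_level = background_level,
                 min_spacing = min_spacing, seed = seed,
                 scale_name = scale_name),
            class = "synthetic_spec")
}

# Greedy multiset of m residues whose mean scale value approximates target.
# Early picks alternate between the nearest value above and below the
# per-residue remainder (keeping the composition diverse instead of
# collapsing onto one or two residues); the last two picks take the nearest
# value outright so the sum lands on target up to quantization.
greedy_motif <- function(target, m, values) {
  letters_out <- character(m)
  s <- 0
  for (j in seq_len(m)) {
    want <- (target * m - s) / (m - j + 1L)
    pool <- values
    if (j < m - 1L) {
      side <- if (j %% 2L == 1L) values >= want else values <= want
      if (any(side)) pool <- values[side]
    }
    pick <- which.min(abs(pool - want))
    letters_out[j] <- names(pool)[pick]
    s <- s + pool[pick]
  }
  letters_out
}

# Most hydrophobic residue at the motif center (so the profile maximum sits
# on the planted center), remaining residues in random order: the window
# mean over the whole motif is order-invariant, but narrower windows see a
# different mix per motif, which keeps the motif width identifiable.
arrange_motif <- function(letters_in, values) {
  m <- length(letters_in)
  imax <- which.max(values[letters_in])
  rest <- letters_in[-imax]
  if (length(rest) > 1L) rest <- sample(rest)
  center <- (m + 1L) %/% 2L
  append(rest, letters_in[imax], after = center - 1L)
}

#' Generate a sequence with planted hydrophobic peaks
#'
#' Builds an amino-acid sequence according to a [synthetic_spec()]:
#' background positions are sampled from a pool of residues whose scale
#' values straddle \code{background_level} (extreme hydrophobics are
#' excluded from the pool so spurious background peaks are rare); each
#' planted motif is a multiset of \code{motif_width} residues chosen by
#' greedy scale-value matching so the windowed mean at the motif center
#' approximates a height drawn from Normal(\code{target_level},
#' \code{level_spread}^2), arranged as a unimodal bump.  Because scale
#' values are discrete, requested heights are never hit exactly; the truth
#' object reports the achieved window means, which are the usable oracle.
#'
#' @param spec A \code{synthetic_spec}.
#' @param background_pool Optional character vector of residue letters for
#'   the background; default: the 6 residues closest in value to
#'   \code{background_level}, excluding the 4 most hydrophobic of the
#'   scale.
#' @return List with \code{record} (a \code{seq_record}, region unset) and
#'   \code{truth} (list with \code{planted_centers},
#'   \code{planted_heights} = achieved window means at the centers, and
#'   \code{requested_heights} = the Normal draws before quantization and
#'   clipping).
#' @examples
#' g <- generate_sequence(synthetic_spec(seed = 42))
#' g$truth$planted_centers
#' @export
generate_sequence <- function(spec, background_pool = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  scale <- load_scale(spec$scale_name)
  vals <- scale$values
  lo <- min(vals); hi <- max(vals)
  if (spec$target_level < lo || spec$target_level > hi)
    stop("target_level ", spec$target_level, " outside the attainable ",
         "range of window means on scale ", scale$name,
         sprintf(" [%.3f, %.3f]", lo, hi), call. = FALSE)
  if (spec$background_level < lo || spec$background_level > hi)
    stop("background_level outside scale range", call. = FALSE)
  m <- spec$motif_width
  half <- (m - 1L) %/% 2L
  with_seed(spec$seed, {
    # background pool: near background_level, extreme hydrophobics excluded
    if (is.null(background_pool)) {
      hydro4 <- names(sort(vals, decreasing = TRUE))[1:4]
      cand <- vals[setdiff(names(vals), hydro4)]
      background_pool <- names(sort(abs(cand - spec$background_level)))[1:6]
    }
    residues <- sample(background_pool, spec$length, replace = TRUE)
    centers <- integer(0)
    requested <- numeric(0)
    if (spec$k > 0L) {
      margin <- m          # keep motifs clear of the sequence ends
      base <- as.integer(round(seq(margin + half, spec$length - margin - half,
                                   length.out = spec$k)))
      if (spec$k > 1L) {
        # keep centers strictly interior to the profile of a width-m window
        amp <- min((min(diff(base)) - spec$min_spacing) %/% 2L,
                   base[1] - (half + 2L),
                   (spec$length - half - 1L) - base[spec$k])
        amp <- max(0L, amp)
        jit <- if (amp > 0L) sample.int(2L * amp + 1L, spec$k,
                                        replace = TRUE) - amp - 1L
               else integer(spec$k)
        centers <- base + jit
      } else centers <- base
      requested <- stats::rnorm(spec$k, spec$target_level, spec$level_spread)
      planted <- pmin(pmax(requested, lo), hi)
      for (i in seq_len(spec$k)) {
        motif <- greedy_motif(planted[i], m, vals)
        motif <- arrange_motif(motif, vals)
        residues[(centers[i] - half):(centers[i] + half)] <- motif
      }
    }
    seqstr <- paste(residues, collapse = "")
    v <- unname(vals[residues])
    achieved <- vapply(centers, function(cc)
      mean(v[(cc - half):(cc + half)]), numeric(1))
    list(record = seq_record(id = sprintf("synthetic_k%d_s%g", spec$k,
                                          spec$level_spread),
                             residues = seqstr, species = "synthetic"),
         truth = list(planted_centers = centers,
                      planted_heights = achieved,
                      requested_heights = requested))
  })
}
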