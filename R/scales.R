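# Hydropathy scale tables and the segment-SASA power-law fitter.

AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Kyte & Doolittle (1982) J. Mol. Biol. 157:105-132, Table 1 ("hydropathy
# index").  First-order scale; positive = hydrophobic.
.KD_VALUES <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Moret & Zebende (2007) Phys. Rev. E 75:011920.  Psi(aa) is the power-law
# exponent of mean segment solvent-accessible surface area versus segment
# length over 9 <= L <= 35; larger exponent = stronger self-similar occlusion
# on folding = more hydrophobic.  Second-order ("fractal") scale.
.MZ_VALUES <- c(
  A = 0.157, R = 0.078, N = 0.113, D = 0.087, C = 0.246,
  Q = 0.105, E = 0.094, G = 0.156, H = 0.152, I = 0.222,
  L = 0.197, K = 0.069, M = 0.221, F = 0.218, P = 0.121,
  S = 0.100, T = 0.135, W = 0.174, Y = 0.222, V = 0.238
)

new_hydropathy_scale <- function(name, values, hydrophobic_is_max = TRUE) {
  values <- unlist(values)
  if (length(values) != 20L ||
      !setequal(names(values), AA_CODES))
    stop("a hydropathy scale needs exactly the 20 standard one-letter codes",
         call. = FALSE)
  if (!all(is.finite(values)))
    stop("all scale values must be finite", call. = FALSE)
  structure(
    list(name = as.character(name),
         values = values[AA_CODES],
         hydrophobic_is_max = isTRUE(hydrophobic_is_max)),
    class = "hydropathy_scale")
}

#' Load a hydropathy scale
#'
#' Returns one of the two scales shipped with the package, oriented so that
#' hydrophobic residues sit at profile maxima ("hydrophobic peaks").
#'
#' \describe{
#'   \item{\code{"MZ"}}{The Moret-Zebende (2007) fractal scale: for each
#'     amino acid, the power-law exponent of mean segment solvent-accessible
#'     surface area (SASA) against segment length \eqn{L} over
#'     \eqn{9 \le L \le 35}, transcribed from Moret & Zebende (2007),
#'     Phys. Rev. E 75, 011920.  Dimensionless exponents in roughly
#'     [0.07, 0.25].}
#'   \item{\code{"KD"}}{The Kyte-Doolittle (1982) hydropathy index,
#'     transcribed from Kyte & Doolittle (1982), J. Mol. Biol. 157, 105-132.
#'     Values in [-4.5, 4.5].}
#' }
#'
#' @param name Scale identifier, \code{"MZ"} or \code{"KD"}.
#' @return A \code{hydropathy_scale}: a list with \code{name}, a named
#'   numeric vector \code{values} over the 20 standard one-letter codes, and
#'   the orientation flag \code{hydrophobic_is_max}.
#' @examples
#' kd <- load_scale("KD")
#' names(which.max(kd$values))  # "I": isoleucine is the most hydrophobic
#' @seealso [rescale()], [read_scale()], [fit_psi_exponent()]
#' @export
load_scale <- function(name) {
  name <- toupper(as.character(name)[1])
  switch(name,
    MZ = new_hydropathy_scale("MZ", .MZ_VALUES),
    KD = new_hydropathy_scale("KD", .KD_VALUES),
    stop("unknown scale '", name, "'; available scales: MZ, KD",
         call. = FALSE))
}

#' @export
print.hydropathy_scale <- function(x, ...) {
  cat("Hydropathy scale '", x$name, "' (hydrophobic at ",
      if (x$hydrophobic_is_max) "maximum" else "minimum", ")\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' Affinely rescale a hydropathy scale
#'
#' Replaces every value \eqn{v} by \eqn{a v + b}.  Useful for plotting
#' scales with very different native ranges (e.g. MZ exponents vs KD units)
#' on a common axis.  Peak positions are unchanged by any affine map with
#' \eqn{a > 0}, and the level deviation statistic is multiplied by
#' \eqn{|a|}; a negative slope flips the hydrophobic orientation.
#'
#' @param scale A \code{hydropathy_scale}.
#' @param a Slope, nonzero.
#' @param b Offset.
#' @return The rescaled \code{hydropathy_scale}.
#' @export
rescale <- function(scale, a, b = 0) {
  stopifnot(inherits(scale, "hydropathy_scale"))
  if (!is.finite(a) || a == 0)
    stop("slope 'a' must be nonzero (a zero slope degenerates the scale)",
         call. = FALSE)
  out <- scale
  out$values <- a * scale$values + b
  if (a < 0) out$hydrophobic_is_max <- !scale$hydrophobic_is_max
  out$name <- sprintf("%s*%g%+g", scale$name, a, b)
  out
}

#' Read a user-supplied hydropathy scale from a text file
#'
#' The file must have two whitespace- or tab-separated columns: the
#' one-letter residue code and its value, one row per residue, all 20
#' standard residues present.  Lines starting with '#' are ignored.
#'
#' @param path Path to the two-column text file.
#' @param name Name to give the scale (default: file name without extension).
#' @param hydrophobic_is_max Orientation flag (default \code{TRUE}).
#' @return A \code{hydropathy_scale}.
#' @export
read_scale <- function(path, name = NULL, hydrophobic_is_max = TRUE) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("code", "value"),
                           colClasses = c("character", "numeric"))
  if (anyDuplicated(tab$code))
    stop("duplicate residue codes in ", path, call. = FALSE)
  v <- stats::setNames(tab$value, toupper(tab$code))
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  new_hydropathy_scale(name, v, hydrophobic_is_max)
}

#' Read a segment-SASA table from TSV
#'
#' Expects columns \code{residue} (one-letter code), \code{L} (odd segment
#' length, residues) and \code{sasa} (mean solvent-accessible surface area
#' of segments of length \code{L} centered on that residue, area units).
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns \code{residue}, \code{L}, \code{sasa}.
#' @examples
#' # synthetic demo table shipped with the package (3 residues, L = 3..45)
#' demo <- system.file("extdata", "synthetic_sasa_demo.tsv",
#'                     package = "hydrolevels")
#' tab <- read_sasa_table(demo)
#' fit_psi_exponent(tab[tab$residue == "C", ])
#' @seealso [fit_psi_exponent()]
#' @export
read_sasa_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("residue", "L", "sasa")
  if (!all(need %in% names(tab)))
    stop("SASA table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  validate_sasa_rows(tab$L, tab$sasa)
  tab[need]
}

validate_sasa_rows <- function(L, sasa) {
  if (any(L %% 2 != 1) || any(L < 3) || any(L > 45))
    stop("segment lengths L must be odd and within [3, 45] (L = 2N + 1)",
         call. = FALSE)
  if (any(!is.finite(sasa)) || any(sasa <= 0))
    stop("all sasa values must be finite and positive", call. = FALSE)
  invisible(TRUE)
}

#' Fit the segment-SASA power-law exponent that defines an MZ-type scale
#'
#' Fits \deqn{\log SASA(L) \sim const - \Psi \log L} by ordinary least
#' squares over segment lengths \code{l_min} to \code{l_max}.  The negated
#' slope \eqn{\Psi} is the hydropathicity exponent: hydrophobic residues
#' lose surface area faster as the segment folds back and occludes them,
#' so they have larger \eqn{\Psi}.  The default range [9, 35] is the
#' self-similar regime of segment SASA in the Protein Data Bank.
#'
#' @param table Data frame with columns \code{L} (odd segment length) and
#'   \code{sasa} (mean segment SASA, > 0); an optional \code{residue} column
#'   must contain a single residue code.
#' @param l_min,l_max Inclusive fitting range for \code{L} (defaults 9, 35).
#' @return An object of class \code{psi_fit} with components \code{psi}
#'   (the exponent), \code{intercept} (the constant, natural-log units),
#'   \code{residue}, \code{n} and the underlying \code{lm} fit.  Supports
#'   \code{coef}, \code{predict} (returns fitted SASA for new \code{L}),
#'   \code{residuals}, \code{summary}, \code{print} and \code{plot}.
#' @examples
#' tab <- data.frame(L = seq(9, 35, 2), sasa = 100 * seq(9, 35, 2)^-0.5)
#' fit <- fit_psi_exponent(tab)
#' coef(fit)  # psi = 0.5, intercept = log(100)
#' @export
fit_psi_exponent <- function(table, l_min = 9, l_max = 35) {
  if (!all(c("L", "sasa") %in% names(table)))
    stop("table must have columns 'L' and 'sasa'", call. = FALSE)
  residue <- NA_character_
  if ("residue" %in% names(table)) {
    res <- unique(table$residue)
    if (length(res) > 1L)
      stop("fit_psi_exponent() fits one residue at a time; got: ",
           paste(res, collapse = ", "), "; see fit_psi_scale()",
           call. = FALSE)
    residue <- res
  }
  validate_sasa_rows(table$L, table$sasa)
  keep <- table$L >= l_min & table$L <= l_max
  if (sum(keep) < 3L)
    stop("need at least 3 rows with ", l_min, " <= L <= ", l_max,
         "; got ", sum(keep), call. = FALSE)
  dat <- data.frame(logL = log(table$L[keep]), logS = log(table$sasa[keep]))
  fit <- stats::lm(logS ~ logL, data = dat)
  structure(
    list(psi = -unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         residue = residue,
         n = nrow(dat),
         l_range = c(l_min, l_max),
         lm = fit),
    class = "psi_fit")
}

#' Fit a full MZ-type scale from a multi-residue segment-SASA table
#'
#' Runs [fit_psi_exponent()] per residue and assembles the 20 exponents
#' into a \code{hydropathy_scale}.
#'
#' @param table Data frame with columns \code{residue}, \code{L}, \code{sasa}
#'   covering all 20 standard residues.
#' @param name Name for the resulting scale.
#' @inheritParams fit_psi_exponent
#' @return A \code{hydropathy_scale} of fitted exponents.
#' @export
fit_psi_scale <- function(table, name = "fitted", l_min = 9, l_max = 35) {
  fits <- lapply(split(table, table$residue), fit_psi_exponent,
                 l_min = l_min, l_max = l_max)
  vals <- vapply(fits, function(f) f$psi, numeric(1))
  new_hydropathy_scale(name, vals, hydrophobic_is_max = TRUE)
}

#' @export
coef.psi_fit <- function(object, ...) {
  c(psi = object$psi, intercept = object$intercept)
}

#' @export
print.psi_fit <- function(x, ...) {
  cat("Segment-SASA power-law fit",
      if (!is.na(x$residue)) paste0(" (residue ", x$residue, ")"), ":\n",
      sep = "")
  cat(sprintf("  log SASA(L) = %.4f - %.4f log L,  %d <= L <= %d,  n = %d\n",
              x$intercept, x$psi, x$l_range[1], x$l_range[2], x$n))
  invisible(x)
}

#' @export
summary.psi_fit <- function(object, ...) {
  s <- summary(object$lm)
  cat("Hydropathicity exponent psi =", format(object$psi, digits = 6), "\n")
  cat("Std. error:", format(s$coefficients[2, 2], digits = 4),
      " R^2:", format(s$r.squared, digits = 4), "\n")
  invisible(s)
}

#' @export
predict.psi_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(unname(exp(stats::fitted(object$lm))))
  if (is.numeric(newdata)) newdata <- data.frame(L = newdata)
  unname(exp(stats::predict(object$lm, data.frame(logL = log(newdata$L)))))
}

#' @export
residuals.psi_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
plot.psi_fit <- function(x, ...) {
  d <- x$lm$model
  graphics::plot(d$logL, d$logS, xlab = "log L", ylab = "log SASA",
                 main = sprintf("psi = %.3f", x$psi), ...)
  graphics::abline(x$lm, lty = 2)
  invisible(x)
}

# Scale values for a residue string; policy for B, Z, X, U, O and other
# codes without a scale entry: error (default) or impute the scale mean.
scale_values_for <- function(residues, scale,
                             na_action = c("error", "impute")) {
  na_action <- match.arg(na_action)
  chars <- strsplit(toupper(residues), "")[[1]]
  v <- unname(scale$values[chars])
  if (anyNA(v)) {
    bad <- which(is.na(v))
    if (na_action == "error")
      stop("residue(s) without a value on scale '", scale$name, "' at ",
           "position(s) ", paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) ", ..." else "",
           " (code(s): ", paste(unique(chars[bad]), collapse = ", "), "); ",
           "set na_action = \"impute\" to use the scale mean",
           call. = FALSE)
    v[bad] <- mean(scale$values)
  }
  v
}
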