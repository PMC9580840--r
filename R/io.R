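# FASTA input, tabular output, profile export and run logging.

parse_fasta_header <- function(header) {
  first <- strsplit(trimws(header), "[ \t]")[[1]][1]
  parts <- strsplit(first, "|", fixed = TRUE)[[1]]
  id <- first; protein <- ""; species <- ""
  if (length(parts) == 3L) {
    id <- parts[2]
    # UniProt entry names look like PROTEIN_SPECIES (e.g. KIF14_HUMAN)
    if (grepl("^[A-Z0-9]+_[A-Z0-9]+$", parts[3])) {
      protein <- sub("_.*$", "", parts[3])
      species <- sub("^[^_]*_", "", parts[3])
    } else {
      protein <- parts[2]
      species <- parts[3]
    }
  }
  list(id = id, protein = protein, species = species)
}

#' Read protein sequences from FASTA
#'
#' Reads a plain or gzipped FASTA file into a list of [seq_record()]s.
#' Sequences are upper-cased and a single terminal '*' is stripped.  When
#' a header is pipe-delimited (\code{db|accession|NAME_SPECIES}, the
#' UniProt convention), the accession becomes the id and the protein and
#' species labels are filled from the entry name; otherwise the first
#' whitespace-delimited token is the id and the labels stay blank.
#'
#' @param path Path to the FASTA file (plain or .gz).
#' @param region Optional \code{c(start, end)} applied to every record, or
#'   a list of such vectors named by record id.
#' @param strict If \code{TRUE}, only the 20 standard residue letters are
#'   accepted; the default additionally tolerates the ambiguity and rare
#'   codes B, Z, X, U, O, J (which still need \code{na_action = "impute"}
#'   at profiling time).  Anything else is always an error.
#' @return List of \code{seq_record}s, named by id.
#' @export
read_fasta <- function(path, region = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  aa <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("non-amino-acid characters in ", path, call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (length(aa) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(aa)
  seqs <- unname(toupper(as.character(aa)))
  seqs <- sub("\\*$", "", seqs)
  allowed <- if (strict) paste(AA_CODES, collapse = "")
             else paste(c(AA_CODES, "B", "Z", "X", "U", "O", "J"),
                        collapse = "")
  bad <- grepl(sprintf("[^%s]", allowed), seqs)
  if (any(bad))
    stop("non-amino-acid characters in record(s): ",
         paste(utils::head(headers[bad], 3), collapse = ", "),
         call. = FALSE)
  meta <- lapply(headers, parse_fasta_header)
  ids <- vapply(meta, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate record ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  recs <- lapply(seq_along(seqs), function(i) {
    reg <- if (is.list(region)) region[[ids[i]]] else region
    seq_record(id = ids[i], residues = seqs[i],
               species = meta[[i]]$species, protein = meta[[i]]$protein,
               region = reg)
  })
  stats::setNames(recs, ids)
}

#' Write results to TSV
#'
#' Species comparisons are written with deviations rounded to 2 decimals
#' (the precision of published comparison tables) plus a full-precision
#' column; profiles are written as position/value pairs at full double
#' precision, with the profile metadata in '#' comment lines, suitable for
#' replotting and for exact round-tripping via [read_profile()].
#'
#' @param x A \code{species_comparison}, \code{hydro_profile}, or plain
#'   data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(x, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path,
                                           call. = FALSE))
  on.exit(close(con))
  if (inherits(x, "hydro_profile")) {
    writeLines(sprintf("# sequence_id=%s scale=%s window=%d hydrophobic_is_max=%s",
                       x$sequence_id, x$scale_name, x$window,
                       x$hydrophobic_is_max), con)
    writeLines("position\tvalue", con)
    if (length(x$values))
      writeLines(sprintf("%d\t%.17g", x$positions, x$values), con)
  } else if (inherits(x, "species_comparison")) {
    y <- as.data.frame(x)
    y$deviation_full <- sprintf("%.17g", y$deviation)
    y$deviation <- sprintf("%.2f", y$deviation)
    y$mean_level <- sprintf("%.4f", y$mean_level)
    utils::write.table(y, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' Re-read an exported profile
#'
#' Inverse of [write_results()] for profiles: reconstructs the
#' \code{hydro_profile}, metadata included, to full double precision.
#'
#' @param path Path written by [write_results()].
#' @return A \code{hydro_profile}.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  metaline <- lines[startsWith(lines, "#")][1]
  kv <- strsplit(strsplit(sub("^#\\s*", "", metaline), " ")[[1]], "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           header = TRUE)
  structure(list(sequence_id = unname(meta["sequence_id"]),
                 scale_name = unname(meta["scale"]),
                 hydrophobic_is_max = identical(unname(meta["hydrophobic_is_max"]),
                                                "TRUE"),
                 window = as.integer(meta["window"]),
                 positions = as.integer(tab$position),
                 values = as.numeric(tab$value)),
            class = "hydro_profile")
}

#' One-line reproducibility log for a fit
#'
#' Formats every parameter that a reported deviation depends on, so a run
#' can be reproduced from its log line.  \code{levelfit} emits this via
#' \code{message()} when \code{options(hydrolevels.verbose = TRUE)}.
#'
#' @param fit A \code{levelfit}.
#' @return The log line, a character scalar.
#' @export
run_log_line <- function(fit) {
  stopifnot(inherits(fit, "levelfit"))
  reg <- region_of(fit$record)
  sprintf(paste0("hydrolevels: id=%s scale=%s window=%d region=%d:%d k=%d ",
                 "definition=%s min_separation=%d polarity=%s deviation=%.6g"),
          fit$record$id, fit$scale$name, fit$params$window, reg[1], reg[2],
          fit$params$k, fit$params$definition, fit$params$min_separation,
          fit$params$polarity, fit$stat$deviation)
}
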