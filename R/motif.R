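# NPxY/F motif logic for integrin beta cytoplasmic tails. Tails carry a
# precursor-numbering offset (start_index) so hits are reported in the
# coordinates used for mutations such as Y783A of human beta-1.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct an integrin tail sequence
#'
#' @param name Tail label (must not contain `|`, which delimits FASTA
#'   header fields).
#' @param residues One-letter amino-acid string (20-letter alphabet).
#' @param start_index Precursor numbering of the first residue (1-based,
#'   counting the signal peptide), e.g. 762 for the human beta-1 tail
#'   construct spanning E762-K798.
#' @param species Species label.
#' @return An object of class `tail_sequence`.
#' @export
tail_sequence <- function(name, residues, start_index = 1L,
                          species = NA_character_) {
  residues <- toupper(residues)
  chars <- strsplit(residues, "")[[1]]
  if (length(chars) == 0) stop("`residues` must be non-empty", call. = FALSE)
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad)) {
    stop("invalid residue character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (start_index < 1) stop("`start_index` must be >= 1", call. = FALSE)
  if (grepl("|", name, fixed = TRUE)) {
    stop("`name` must not contain '|'", call. = FALSE)
  }
  structure(list(name = name, residues = residues,
                 start_index = as.integer(start_index), species = species),
            class = "tail_sequence")
}

#' @export
print.tail_sequence <- function(x, ...) {
  cat(sprintf("<tail_sequence> %s (%s), residues %d-%d\n%s\n",
              x$name, x$species, x$start_index,
              x$start_index + nchar(x$residues) - 1L, x$residues))
  invisible(x)
}

# Overlapping matches of a 4-residue pattern; returns 1-based relative
# start positions.
match_starts <- function(residues, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), residues, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Find NPxY/F-class motifs in an integrin tail
#'
#' Scans for the two talin/kindlin-associated four-residue motifs:
#' the membrane-proximal class `N-P-x-[Y/F]` and the membrane-distal class
#' `N-x-x-[Y/F]`. The first `NPx[Y/F]` match is reported as the
#' membrane-proximal hit, unless it is the last `Nxx[Y/F]` match of the
#' tail and lies in the C-terminal half, in which case it is classified as
#' membrane-distal (this handles tails whose distal motif is itself of
#' `NPxY` form after the proximal site has been mutated away). The first
#' `Nxx[Y/F]` match after the proximal hit -- or, with no proximal hit,
#' the first in the C-terminal half -- is the membrane-distal hit. Each
#' occurrence is reported under exactly one class.
#'
#' @param tail A [tail_sequence()].
#' @return Data frame with columns `motif_class`
#'   (`"membrane_proximal"`/`"membrane_distal"`), `start`, `end`
#'   (precursor coordinates, `end = start + 3`), `terminal_residue` and
#'   `sequence`; zero rows when no motif is present.
#' @examples
#' b1 <- tail_sequence("ITGB1", "EFAKFEKEKMNAKWDTGENPIYKSAVTTVVNPKYEGK", 762)
#' find_motifs(b1)
#' @export
find_motifs <- function(tail) {
  stopifnot(inherits(tail, "tail_sequence"))
  res <- tail$residues
  L <- nchar(res)
  loose <- match_starts(res, "N..[YF]")
  np <- match_starts(res, "NP.[YF]")

  proximal <- integer(0)
  if (length(np)) {
    cand <- np[1]
    last_loose <- max(loose)
    if (!(cand == last_loose && cand > L / 2)) proximal <- cand
  }
  distal <- integer(0)
  if (length(proximal)) {
    later <- loose[loose > proximal]
    if (length(later)) distal <- later[1]
  } else {
    cterm <- loose[loose > L / 2]
    if (length(cterm)) distal <- cterm[1]
  }

  hit_row <- function(rel, class) {
    data.frame(
      motif_class = class,
      start = tail$start_index + rel - 1L,
      end = tail$start_index + rel + 2L,
      terminal_residue = substr(res, rel + 3L, rel + 3L),
      sequence = substr(res, rel, rel + 3L),
      stringsAsFactors = FALSE
    )
  }
  rows <- list()
  if (length(proximal)) rows <- c(rows, list(hit_row(proximal, "membrane_proximal")))
  if (length(distal)) rows <- c(rows, list(hit_row(distal, "membrane_distal")))
  if (length(rows)) do.call(rbind, rows) else
    data.frame(motif_class = character(), start = integer(),
               end = integer(), terminal_residue = character(),
               sequence = character(), stringsAsFactors = FALSE)
}

#' Apply a point mutation in precursor coordinates
#'
#' @param tail A [tail_sequence()].
#' @param spec Mutation string such as `"Y783A"`: reference residue,
#'   precursor position, replacement residue.
#' @return A new `tail_sequence` with the residue replaced and the name
#'   suffixed with the mutation spec.
#' @section Errors: A position outside the tail, or a reference residue
#'   that does not match the sequence at that position, raises an error
#'   (guarding against numbering-offset mistakes).
#' @examples
#' b1 <- tail_sequence("ITGB1", "EFAKFEKEKMNAKWDTGENPIYKSAVTTVVNPKYEGK", 762)
#' apply_mutation(b1, "Y783A")
#' @export
apply_mutation <- function(tail, spec) {
  stopifnot(inherits(tail, "tail_sequence"))
  m <- regmatches(spec, regexec("^([A-Z])([0-9]+)([A-Z])$", spec))[[1]]
  if (length(m) != 4) {
    stop("mutation spec must look like 'Y783A'", call. = FALSE)
  }
  ref <- m[2]; pos <- as.integer(m[3]); alt <- m[4]
  L <- nchar(tail$residues)
  if (pos < tail$start_index || pos > tail$start_index + L - 1L) {
    stop("position ", pos, " is outside the tail (",
         tail$start_index, "-", tail$start_index + L - 1L, ")",
         call. = FALSE)
  }
  rel <- pos - tail$start_index + 1L
  have <- substr(tail$residues, rel, rel)
  if (have != ref) {
    stop("reference residue mismatch at position ", pos, ": sequence has ",
         have, ", spec says ", ref, call. = FALSE)
  }
  residues <- tail$residues
  substr(residues, rel, rel) <- alt
  tail_sequence(paste(tail$name, spec), residues, tail$start_index,
                tail$species)
}

#' Motif presence/absence table for a set of tails
#'
#' @param tails List of [tail_sequence()] objects (at least one).
#' @return Data frame with one row per tail: `name`, `species`,
#'   `membrane_proximal`, `membrane_distal` (logical), and
#'   `proximal_terminal` (the Y/F terminating the proximal motif, or NA).
#' @export
motif_presence_table <- function(tails) {
  if (length(tails) == 0) stop("at least one tail is required", call. = FALSE)
  do.call(rbind, lapply(tails, function(tl) {
    hits <- find_motifs(tl)
    prox <- hits[hits$motif_class == "membrane_proximal", ]
    data.frame(
      name = tl$name, species = tl$species,
      membrane_proximal = nrow(prox) > 0,
      membrane_distal = any(hits$motif_class == "membrane_distal"),
      proximal_terminal = if (nrow(prox)) prox$terminal_residue[1] else
        NA_character_,
      stringsAsFactors = FALSE
    )
  }))
}

#' Read integrin tails from FASTA
#'
#' Headers follow `name|start_index|species`. Files written by
#' [write_tail_fasta()] round-trip exactly.
#'
#' @param path FASTA file.
#' @return List of `tail_sequence` objects.
#' @export
read_tail_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  lapply(seq_along(set), function(i) {
    parts <- strsplit(names(set)[i], "|", fixed = TRUE)[[1]]
    tail_sequence(
      name = parts[1],
      residues = as.character(set[[i]]),
      start_index = if (length(parts) >= 2) as.integer(parts[2]) else 1L,
      species = if (length(parts) >= 3) parts[3] else NA_character_
    )
  })
}

#' Write integrin tails to FASTA
#'
#' @param tails List of `tail_sequence` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tail_fasta <- function(tails, path) {
  seqs <- Biostrings::AAStringSet(vapply(tails, `[[`, "", "residues"))
  names(seqs) <- vapply(tails, function(tl) {
    paste(tl$name, tl$start_index, tl$species, sep = "|")
  }, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Packaged integrin beta tail fixtures
#'
#' Loads the tail sequences shipped with the package. The human beta-1,
#' beta-2 and beta-3 tails are reconstructed from the cloning-primer
#' translations of the chimeric constructs; the remaining entries (human
#' beta-5 to beta-8 and the two Capsaspora owczarzaki tails) live in a
#' file labelled `synthetic` because they are best-effort reconstructions
#' that preserve the documented motif architecture rather than
#' database-verified sequences. The beta-4 tail is excluded because of its
#' extraordinary length.
#'
#' @return Named list of `tail_sequence` objects.
#' @export
optic_tail_fixtures <- function() {
  files <- c(
    system.file("extdata", "tails_human_core.fa", package = "opticr"),
    system.file("extdata", "tails_extended_synthetic.fa", package = "opticr")
  )
  tails <- unlist(lapply(files, read_tail_fasta), recursive = FALSE)
  names(tails) <- vapply(tails, `[[`, "", "name")
  tails
}
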