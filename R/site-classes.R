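#' Site degeneracy classes
#'
#' Coding positions are classified by codon degeneracy under the standard
#' genetic code: a position is fourfold degenerate (`"4D"`) when every
#' nucleotide substitution at that position is synonymous, zerofold
#' degenerate (`"0D"`) when every substitution changes the amino acid, and
#' `"other"` for the intermediate (two- and threefold) cases. Positions in
#' codons containing `N` or other ambiguity codes, and positions in stop
#' codons, are `"unclassified"` and enter neither diversity estimate.
#'
#' @name site_classes
#' @keywords internal
NULL

# levels used everywhere downstream
SITE_CLASSES <- c("4D", "0D", "other", "unclassified")

#' Classify one codon position by degeneracy
#'
#' @param codon Character vector of 3-letter codons (case-insensitive).
#' @param position Codon position, 1, 2 or 3 (recycled against `codon`).
#'
#' @return Character vector over `"4D"`, `"0D"`, `"other"`,
#'   `"unclassified"`. Stop codons and codons with ambiguity codes are
#'   `"unclassified"`.
#'
#' @examples
#' classify_codon("GCT", 3) # alanine third position: "4D"
#' classify_codon("ATG", 1) # "0D"
#' @export
classify_codon <- function(codon, position) {
  codon <- toupper(codon)
  stopifnot(all(position %in% 1:3))
  n <- max(length(codon), length(position))
  codon <- rep_len(codon, n)
  position <- rep_len(position, n)
  key <- paste0(codon, position)
  out <- unname(degeneracy_table()[key])
  out[is.na(out)] <- "unclassified"
  out
}

# Degeneracy lookup for all 64 codons x 3 positions, built once from the
# standard genetic code.
degeneracy_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) {
      return(tab)
    }
    code <- Biostrings::GENETIC_CODE
    bases <- c("A", "C", "G", "T")
    res <- character(0)
    for (codon in names(code)) {
      aa <- code[[codon]]
      for (pos in 1:3) {
        if (aa == "*") {
          cls <- "unclassified"
        } else {
          alt <- setdiff(bases, substr(codon, pos, pos))
          mut <- vapply(alt, function(b) {
            x <- codon
            substr(x, pos, pos) <- b
            code[[x]]
          }, character(1))
          syn <- sum(mut == aa)
          cls <- if (syn == 3L) "4D" else if (syn == 0L) "0D" else "other"
        }
        res[paste0(codon, pos)] <- cls
      }
    }
    tab <<- res
    tab
  }
})

#' Classify every position of a coding sequence
#'
#' Walks the sequence codon by codon in the given reading frame and labels
#' each position with its degeneracy class. A trailing incomplete codon is
#' kept in the output but `"unclassified"` (with a warning), as are all
#' positions of codons containing non-ACGT characters. Internal stop codons
#' are classified `"unclassified"` and reported via a warning.
#'
#' @param seq A single nucleotide string over `A,C,G,T,N` (case-insensitive).
#' @param cds_id Identifier carried into the output.
#' @param frame Reading-frame offset (0, 1 or 2); bases before the frame
#'   start are `"unclassified"`.
#'
#' @return A tibble with columns `cds_id`, `pos` (0-based position within
#'   the sequence) and `class`, one row per input base.
#'
#' @examples
#' classify_cds("ATGGCT", "cds1")
#' @export
classify_cds <- function(seq, cds_id = "cds", frame = 0L) {
  stopifnot(length(seq) == 1L, is.character(seq))
  seq <- toupper(seq)
  len <- nchar(seq)
  if (len == 0L) {
    stop("empty coding sequence for '", cds_id, "'", call. = FALSE)
  }
  stopifnot(frame %in% 0:2)
  class <- rep("unclassified", len)
  n_codons <- (len - frame) %/% 3L
  if ((len - frame) %% 3L != 0L) {
    warning("'", cds_id, "': trailing incomplete codon left unclassified",
      call. = FALSE
    )
  }
  if (n_codons > 0L) {
    starts <- frame + 3L * (seq_len(n_codons) - 1L) + 1L
    codons <- substring(seq, starts, starts + 2L)
    n_stop <- sum(codons %in% c("TAA", "TAG", "TGA"))
    if (n_stop > 0L) {
      warning("'", cds_id, "': ", n_stop, " stop codon(s) left unclassified",
        call. = FALSE
      )
    }
    for (p in 1:3) {
      class[starts + p - 1L] <- classify_codon(codons, p)
    }
  }
  tibble::tibble(
    cds_id = cds_id,
    pos = 0:(len - 1L),
    class = class
  )
}

#' Classify all sequences of a CDS FASTA file
#'
#' @param path Path to a FASTA file of in-frame coding sequences.
#' @return A tibble as [classify_cds()], rows stacked over records.
#' @export
classify_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  purrr::list_rbind(purrr::imap(
    as.character(seqs),
    function(s, id) classify_cds(s, cds_id = id)
  ))
}

#' Write a site classification as TSV
#'
#' @param classes Tibble from [classify_cds()] / [classify_fasta()].
#' @param path Output path; columns `cds_id`, `pos`, `class`.
#' @export
write_classes_tsv <- function(classes, path) {
  utils::write.table(classes[, c("cds_id", "pos", "class")],
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_classes_tsv
#' @export
read_classes_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path,
    header = TRUE, sep = "\t",
    colClasses = c("character", "integer", "character")
  ))
}
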