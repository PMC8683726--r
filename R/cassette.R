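#' Build a C-less cassette template for single-round transcription assays
#'
#' Models the promoter-proximal template used in the reconstituted Pol I
#' transcription assay: the transcript encodes no cytosine until one past
#' the halt position, so that withholding CTP synchronises polymerases at
#' the halt point (+55 by default) and adding CTP releases them to
#' transcribe the remainder of the template (800 nt by default).
#'
#' @param transcript_length Transcript length in nt (default 800).
#' @param halt_position Last C-less transcript position (default 55); the
#'   first C is at `halt_position + 1`.
#' @param seed Integer seed for the random sequence fill.
#' @return An object of class `cless_template`: a list with
#'   `transcript_length`, `halt_position`, `first_C_position`,
#'   `transcript_sequence` (RNA alphabet) and `template_dna` (the
#'   template-strand DNA, reverse complement of the transcript).
#' @export
build_cless_template <- function(transcript_length = 800L,
                                 halt_position = 55L,
                                 seed = 1L) {
  if (halt_position < 1L || halt_position >= transcript_length) {
    stop_invalid("`halt_position` must satisfy 1 <= halt_position < transcript_length.")
  }
  transcript <- with_seed(seed, {
    head_part <- sample(c("A", "U", "G"), halt_position, replace = TRUE)
    tail_len <- transcript_length - halt_position - 1L
    tail_part <- sample(c("A", "C", "G", "U"), tail_len, replace = TRUE)
    c(head_part, "C", tail_part)
  })
  rna <- paste(transcript, collapse = "")
  dna <- chartr("U", "T", rna)
  template <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(dna))
  )
  structure(
    list(
      transcript_length = as.integer(transcript_length),
      halt_position = as.integer(halt_position),
      first_C_position = as.integer(halt_position + 1L),
      transcript_sequence = rna,
      template_dna = template
    ),
    class = "cless_template"
  )
}

#' @export
print.cless_template <- function(x, ...) {
  cat(sprintf(
    "<cless_template> %d nt transcript, halt at +%d, first C at +%d\n",
    x$transcript_length, x$halt_position, x$first_C_position
  ))
  invisible(x)
}
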