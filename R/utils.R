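# IUPAC nucleotide codes and the bases each denotes
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Reverse complement of DNA strings
#'
#' Vectorised; IUPAC ambiguity codes are complemented to their
#' complementary sets (R <-> Y, etc.).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# evaluate code under a temporary RNG state seeded with `seed`;
# NULL seed leaves the RNG stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Convert between numeric Phred scores and Phred+33 strings
#'
#' Quality vectors travel through the package as Phred+33 encoded
#' strings (the FASTQ convention); these helpers convert to and from
#' integer score vectors.
#'
#' @param q For `phred_to_string`, an integer vector of Phred scores;
#'   for `string_to_phred`, a single Phred+33 encoded string.
#' @return A single string, or an integer vector.
#' @export
phred_to_string <- function(q) {
  intToUtf8(as.integer(q) + 33L)
}

#' @rdname phred_to_string
#' @export
string_to_phred <- function(q) {
  if (length(q) != 1L) stop("string_to_phred expects a single string")
  if (!nzchar(q)) return(integer(0))
  utf8ToInt(q) - 33L
}

# sample() without the scalar-x surprise
resample <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each base independently with probability `rate`, always to a
# different base; returns the mutated string
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) {
    alt <- setdiff(c("A", "C", "G", "T"), ch[i])
    ch[i] <- alt[sample.int(3L, 1L)]
  }
  paste(ch, collapse = "")
}
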