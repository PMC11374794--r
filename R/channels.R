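#' @keywords internal
DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA strings over A/C/G/T.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Canonical SBS96 channel labels
#'
#' The 96-channel single-base-substitution scheme: 6 pyrimidine-centred
#' substitution classes (C>A, C>G, C>T, T>A, T>C, T>G) times 16 flanking
#' contexts. Labels have the form `"X[R>A]Y"`. The order is fixed and
#' treated as canonical throughout the package: substitution class major,
#' then 5' flank (A,C,G,T), then 3' flank (A,C,G,T).
#'
#' @return character vector of length 96.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(96)
  i <- 0L
  for (s in subs) {
    for (f5 in DNA_BASES) {
      for (f3 in DNA_BASES) {
        i <- i + 1L
        out[i] <- paste0(f5, "[", s, "]", f3)
      }
    }
  }
  out
}

#' Canonical ID83 channel labels
#'
#' The 83-channel COSMIC-style indel scheme. Labels encode
#' `size:type:context:lengthclass`:
#' \itemize{
#'   \item 1bp deletions in C and T homopolymers, run-length classes 1..5,6+
#'     (12 channels; A/G events are complement-collapsed onto T/C);
#'   \item 1bp insertions in C and T homopolymers, classes 0..4,5+ (12);
#'   \item >=2bp deletions at repeats, size 2,3,4,5+ by unit-count 1..5,6+ (24);
#'   \item >=2bp insertions at repeats, size 2,3,4,5+ by unit-count 0..4,5+ (24);
#'   \item deletions with microhomology, size 2 (MH 1), 3 (MH 1-2), 4 (MH 1-3),
#'     5+ (MH 1-4,5+) (11).
#' }
#' The deletion homopolymer-length classes start at 1 (the deleted base itself)
#' and the insertion classes at 0 (no pre-existing identical neighbour).
#'
#' @return character vector of length 83.
#' @export
id83_channels <- function() {
  out <- character(0)
  for (b in c("C", "T")) {
    out <- c(out, paste0("1:Del:", b, ":", c(1:5, "6+")))
  }
  for (b in c("C", "T")) {
    out <- c(out, paste0("1:Ins:", b, ":", c(0:4, "5+")))
  }
  sizes <- c("2", "3", "4", "5+")
  for (s in sizes) {
    out <- c(out, paste0(s, ":Del:R:", c(1:5, "6+")))
  }
  for (s in sizes) {
    out <- c(out, paste0(s, ":Ins:R:", c(0:4, "5+")))
  }
  out <- c(out,
           "2:Del:M:1",
           paste0("3:Del:M:", 1:2),
           paste0("4:Del:M:", 1:3),
           paste0("5+:Del:M:", c(1:4, "5+")))
  out
}

#' Channel labels for a channel set
#'
#' @param channel_set `"SBS96"` or `"ID83"`.
#' @return character vector of canonical channel labels.
#' @export
channel_labels <- function(channel_set = c("SBS96", "ID83")) {
  channel_set <- match.arg(channel_set)
  if (channel_set == "SBS96") sbs96_channels() else id83_channels()
}
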