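TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

# resolve transition-implied alleles against a reference segment
materialize_alleles <- function(profile, reference) {
  ref <- check_reference(reference, profile$window)
  offsets <- profile$positions - profile$window[1] + 1L
  ref_bases <- substring(ref, offsets, offsets)
  out <- profile$alleles
  implied <- is.na(out)
  out[implied] <- TRANSITION_PARTNER[ref_bases[implied]]
  clash <- !implied & out == ref_bases
  if (any(clash))
    stop(sprintf("profile '%s': explicit allele equals the reference base at %s",
                 profile$sample_id,
                 paste(profile$positions[clash], collapse = ", ")))
  out
}

check_reference <- function(reference, window) {
  stopifnot(is.character(reference), length(reference) == 1L)
  reference <- toupper(reference)
  L <- window[2] - window[1] + 1L
  if (nchar(reference) != L)
    stop(sprintf("reference length %d does not match window length %d",
                 nchar(reference), L))
  if (grepl("[^ACGT]", reference))
    stop("reference contains non-ACGT characters (ambiguity codes unsupported)")
  reference
}

#' Materialize a variant profile as a nucleotide sequence
#'
#' Substitutes the profile's derived alleles into the reference segment.
#' Transition-implied variants substitute the transition partner of the
#' reference base (A<->G, C<->T).
#'
#' @param profile A \code{\link{variant_profile}}.
#' @param reference Reference segment covering the profile's window.
#' @return Character string of the same length as \code{reference}.
#' @export
profile_to_sequence <- function(profile, reference = hvr1_reference()) {
  ref <- check_reference(reference, profile$window)
  if (!length(profile$positions)) return(ref)
  alleles <- materialize_alleles(profile, ref)
  chars <- strsplit(ref, "")[[1]]
  chars[profile$positions - profile$window[1] + 1L] <- alleles
  paste(chars, collapse = "")
}

#' Recover a variant profile from a sequence
#'
#' Compares a sequence against the reference over the window and records
#' a variant with an explicit allele at every mismatching position.
#'
#' @param seq Nucleotide string, same length as \code{reference}.
#' @param reference Reference segment.
#' @param sample_id Identifier for the resulting profile.
#' @param window Inclusive window the sequence covers.
#' @return A \code{\link{variant_profile}} with explicit alleles.
#' @export
sequence_to_profile <- function(seq, reference = hvr1_reference(),
                                sample_id = "seq", window = HVR1_WINDOW) {
  ref <- check_reference(reference, window)
  seq <- toupper(seq)
  if (nchar(seq) != nchar(ref)) stop("sequence and reference lengths differ")
  if (grepl("[^ACGT]", seq))
    stop("sequence contains ambiguity codes (unsupported)")
  s <- strsplit(seq, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  idx <- which(s != r)
  variant_profile(sample_id, positions = window[1] + idx - 1L,
                  alleles = s[idx], window = window)
}
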