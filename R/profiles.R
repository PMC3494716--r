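#' @importFrom stats cmdscale dist qbinom rbinom rpois runif setNames
#' @importFrom utils read.delim combn head
NULL

HVR1_WINDOW <- c(16051L, 16400L)

#' HVS-I variant profile
#'
#' A variant profile records a sample's differences from the reference
#' sequence over an inclusive HVS-I window (by default rCRS positions
#' 16051--16400, 350 sites).  Each variant is a 1-based rCRS position with
#' either an explicit derived allele or, when the allele is \code{NA}, a
#' transition implied relative to the reference base (the convention of
#' published HVS-I shorthand tables, which print positions only).
#'
#' @param sample_id Sample identifier.
#' @param positions Integer vector of rCRS positions inside the window.
#' @param alleles Optional character vector, one per position, each one of
#'   \code{"A","C","G","T"} or \code{NA} for a transition-implied allele.
#' @param window Length-2 integer vector, inclusive window bounds.
#' @return An object of class \code{"variant_profile"}.
#' @examples
#' variant_profile("AE05.T2", c(16223, 16292, 16362))
#' @export
variant_profile <- function(sample_id, positions = integer(),
                            alleles = NULL, window = HVR1_WINDOW) {
  stopifnot(length(sample_id) == 1L, length(window) == 2L,
            window[1] <= window[2])
  positions <- as.integer(positions)
  if (anyNA(positions)) stop("positions must be integers")
  if (any(positions < window[1] | positions > window[2]))
    stop(sprintf("profile '%s': position(s) %s outside window [%d,%d]",
                 sample_id,
                 paste(positions[positions < window[1] | positions > window[2]],
                       collapse = ", "),
                 window[1], window[2]))
  if (anyDuplicated(positions))
    stop(sprintf("profile '%s': duplicated position(s) %s", sample_id,
                 paste(unique(positions[duplicated(positions)]), collapse = ", ")))
  if (is.null(alleles)) alleles <- rep(NA_character_, length(positions))
  alleles <- toupper(as.character(alleles))
  if (length(alleles) != length(positions))
    stop("alleles must align with positions")
  if (!all(is.na(alleles) | alleles %in% c("A", "C", "G", "T")))
    stop(sprintf("profile '%s': unsupported allele code (indels/heteroplasmies are rejected)",
                 sample_id))
  ord <- order(positions)
  structure(list(sample_id = as.character(sample_id),
                 window = as.integer(window),
                 positions = positions[ord],
                 alleles = alleles[ord]),
            class = "variant_profile")
}

#' @export
print.variant_profile <- function(x, ...) {
  cat(sprintf("<variant_profile> %s  [%d-%d]  %d variant(s)\n",
              x$sample_id, x$window[1], x$window[2], length(x$positions)))
  if (length(x$positions))
    cat(" ", paste0(x$positions,
                    ifelse(is.na(x$alleles), "", x$alleles),
                    collapse = " "), "\n")
  invisible(x)
}

window_length <- function(profile) diff(profile$window) + 1L

# canonical haplotype identity: positions + allele codes (NA = implied transition)
haplotype_key <- function(profile) {
  if (!length(profile$positions)) return("")
  paste0(profile$positions,
         ifelse(is.na(profile$alleles), "", profile$alleles),
         collapse = "-")
}

#' One restriction-marker observation
#'
#' @param enzyme Restriction enzyme name (e.g. \code{"HaeIII"}).
#' @param position rCRS position of the polymorphic site.
#' @param state One of \code{"present"}, \code{"absent"}, \code{"missing"}.
#' @return A one-row data frame; bind several to form a sample's RFLP panel.
#' @export
rflp_observation <- function(enzyme, position, state) {
  state <- match.arg(state, c("present", "absent", "missing"))
  data.frame(enzyme = as.character(enzyme), position = as.integer(position),
             state = state, stringsAsFactors = FALSE)
}

validate_rflp <- function(rflp, sample_id = "?") {
  if (is.null(rflp) || !nrow(rflp)) {
    return(data.frame(enzyme = character(), position = integer(),
                      state = character(), stringsAsFactors = FALSE))
  }
  stopifnot(all(c("enzyme", "position", "state") %in% names(rflp)))
  if (!all(rflp$state %in% c("present", "absent", "missing")))
    stop(sprintf("sample '%s': RFLP state must be present/absent/missing", sample_id))
  if (anyDuplicated(rflp[c("enzyme", "position")]))
    stop(sprintf("sample '%s': duplicated (enzyme, position) RFLP pair", sample_id))
  rflp
}

#' A typed ancient-DNA sample record
#'
#' Bundles a sample's HVS-I profile, its coding-region RFLP panel and its
#' archaeological metadata (site, period), plus the haplogroup labels as
#' originally reported, if any.
#'
#' @param sample_id,site,period Metadata; \code{period} is typically
#'   \code{"Bronze"} or \code{"Iron"}.
#' @param profile A \code{\link{variant_profile}}.
#' @param rflp Data frame of RFLP observations (columns enzyme, position,
#'   state); missing markers may simply be omitted.
#' @param reported_hvr1,reported_rflp Haplogroup labels as printed in the
#'   source table (optional).
#' @return An object of class \code{"sample_record"}.
#' @export
sample_record <- function(sample_id, site = NA_character_, period,
                          profile, rflp = NULL,
                          reported_hvr1 = NA_character_,
                          reported_rflp = NA_character_) {
  stopifnot(inherits(profile, "variant_profile"), !is.na(period))
  structure(list(sample_id = as.character(sample_id),
                 site = as.character(site),
                 period = as.character(period),
                 profile = profile,
                 rflp = validate_rflp(rflp, sample_id),
                 reported_hvr1 = as.character(reported_hvr1),
                 reported_rflp = as.character(reported_rflp)),
            class = "sample_record")
}

#' A labelled collection of sample records
#'
#' @param label Population label (e.g. \code{"PAZMG1"}).
#' @param records List of \code{\link{sample_record}} objects (length >= 1).
#' @param region,period Optional metadata.
#' @return An object of class \code{"population_dataset"}.
#' @export
population_dataset <- function(label, records, region = NA_character_,
                               period = NA_character_) {
  if (!nzchar(label)) stop("population label must be non-empty")
  if (!length(records)) stop("population must contain at least one record")
  stopifnot(all(vapply(records, inherits, TRUE, "sample_record")))
  structure(list(label = as.character(label), records = records,
                 region = as.character(region), period = as.character(period)),
            class = "population_dataset")
}

#' @export
print.population_dataset <- function(x, ...) {
  cat(sprintf("<population_dataset> %s  N=%d  (%s)\n",
              x$label, length(x$records),
              paste(unique(vapply(x$records, `[[`, "", "period")), collapse = "/")))
  invisible(x)
}

#' Extract the variant profiles of a population
#'
#' @param pop A \code{\link{population_dataset}}, a list of
#'   \code{\link{sample_record}}s, or a list of profiles.
#' @return List of \code{\link{variant_profile}} objects.
#' @export
pop_profiles <- function(pop) {
  if (inherits(pop, "population_dataset")) pop <- pop$records
  lapply(pop, function(r) {
    if (inherits(r, "sample_record")) r$profile
    else if (inherits(r, "variant_profile")) r
    else stop("expected sample_record or variant_profile elements")
  })
}

assert_common_window <- function(profiles) {
  w <- vapply(profiles, function(p) paste(p$window, collapse = ":"), "")
  if (length(unique(w)) > 1L)
    stop("profiles do not share a common window")
  invisible(profiles)
}
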