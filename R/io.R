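extdata <- function(file) {
  path <- system.file("extdata", file, package = "altaimt")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}

#' Parse a shorthand HVS-I variant table
#'
#' Reads a sample table in the layout of published ancient-mtDNA reports:
#' one row per sample with an id, site, period, a comma-separated list of
#' 3-digit shorthand HVS-I positions (printed "minus 16000"), and one
#' column per RFLP marker named \code{<Enzyme>_<position>} holding
#' \code{"+"} (site present), \code{"-"} (site absent) or blank (not
#' typed).  Shorthand position \code{p} becomes rCRS position
#' \code{16000 + p}; blanks become \code{state = "missing"}.
#'
#' @param x A data frame, or the path of a TSV file with the columns
#'   described above (\code{id}, \code{site}, \code{period},
#'   \code{hvr1_variants}, marker columns, optional \code{reported_hvr1} /
#'   \code{reported_rflp}).
#' @param window Inclusive HVS-I window; shorthand positions must fall in
#'   \code{window - 16000}.
#' @return A list of \code{\link{sample_record}} objects.
#' @examples
#' tab <- data.frame(id = "X", site = "S", period = "Iron",
#'                   hvr1_variants = "223, 292, 362")
#' parse_variant_table(tab)[[1]]$profile
#' @export
parse_variant_table <- function(x, window = HVR1_WINDOW) {
  df <- if (is.character(x)) {
    read.delim(x, check.names = FALSE, colClasses = "character",
               na.strings = NULL)
  } else as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("id", "period", "hvr1_variants")
  if (!all(need %in% names(df)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  marker_cols <- grep("^[A-Za-z0-9]+_[0-9]+$", names(df), value = TRUE)
  lo <- window[1] - 16000L; hi <- window[2] - 16000L
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    raw <- trimws(strsplit(as.character(row$hvr1_variants), ",")[[1]])
    raw <- raw[nzchar(raw)]
    if (length(raw)) {
      if (!all(grepl("^[0-9]{3}$", raw)))
        stop(sprintf("row '%s': malformed shorthand position(s): %s",
                     row$id, paste(raw[!grepl("^[0-9]{3}$", raw)], collapse = ", ")))
      short <- as.integer(raw)
      if (any(short < lo | short > hi))
        stop(sprintf("row '%s': shorthand position(s) %s outside [%03d,%03d]",
                     row$id,
                     paste(sprintf("%03d", short[short < lo | short > hi]),
                           collapse = ", "),
                     lo, hi))
      pos <- 16000L + short
    } else pos <- integer()
    profile <- variant_profile(row$id, pos, window = window)
    rflp <- NULL
    if (length(marker_cols)) {
      cells <- vapply(marker_cols, function(cc) {
        v <- as.character(row[[cc]])
        if (is.na(v)) "" else trimws(v)
      }, "")
      enzyme <- sub("_[0-9]+$", "", marker_cols)
      position <- as.integer(sub("^.*_", "", marker_cols))
      state <- ifelse(cells == "+", "present",
                      ifelse(cells %in% c("-", "−"), "absent", "missing"))
      bad <- !cells %in% c("", "+", "-", "−")
      if (any(bad))
        stop(sprintf("row '%s': unrecognized RFLP cell '%s'", row$id,
                     cells[bad][1]))
      rflp <- data.frame(enzyme = enzyme, position = position, state = state,
                         stringsAsFactors = FALSE)
    }
    sample_record(row$id,
                  site = if ("site" %in% names(row)) row$site else NA,
                  period = row$period, profile = profile, rflp = rflp,
                  reported_hvr1 = if ("reported_hvr1" %in% names(row))
                    row$reported_hvr1 else NA,
                  reported_rflp = if ("reported_rflp" %in% names(row))
                    row$reported_rflp else NA)
  })
}

#' The Bronze/Iron Age Mongolian Altai fixture
#'
#' Loads the packaged sample table of 19 ancient individuals from four
#' Mongolian Altai burial sites (3 Bronze Age, 16 Iron Age / Pazyryk),
#' each typed over HVS-I 16051--16400 and a panel of 10 coding-region
#' RFLP markers.
#'
#' @return \code{altai_pazyryk()}: list of 19 \code{\link{sample_record}}s.
#' @export
altai_pazyryk <- function() {
  parse_variant_table(extdata("altai_table2.tsv"))
}

#' @rdname altai_pazyryk
#' @details \code{altai_populations()} splits the fixture by period into
#'   the two study populations: \code{AMGBR} (Bronze Age, N=3) and
#'   \code{PAZMG1} (Iron Age Pazyryk, N=16), plus the pooled set.
#' @return \code{altai_populations()}: named list of
#'   \code{\link{population_dataset}}s (\code{bronze}, \code{iron},
#'   \code{all}).
#' @export
altai_populations <- function() {
  recs <- altai_pazyryk()
  period <- vapply(recs, `[[`, "", "period")
  list(bronze = population_dataset("AMGBR", recs[period == "Bronze"],
                                   region = "Mongolia (Altai)", period = "Bronze"),
       iron = population_dataset("PAZMG1", recs[period == "Iron"],
                                 region = "Mongolia (Altai)", period = "Iron"),
       all = population_dataset("Altai", recs, region = "Mongolia (Altai)"))
}

#' Packaged HVS-I reference segment
#'
#' Returns the packaged 350-bp reference over the default window.  This is
#' a \emph{synthetic} stand-in segment (the package ships no rCRS
#' sequence); every statistic in the package operates on variant sets, so
#' the reference only anchors sequence materialization and round-trips.
#' Supply your own rCRS segment to work with real sequences.
#'
#' @return Single character string of length 350.
#' @export
hvr1_reference <- function() {
  unname(read_fasta(extdata("synthetic_hvr1_reference.fasta"))[1])
}

#' Read and write FASTA
#'
#' Thin wrappers around \pkg{Biostrings} returning/accepting plain named
#' character vectors, line-wrapped at 70 columns on output.
#'
#' @param path File path.
#' @param sequences Named character vector of nucleotide sequences.
#' @return \code{read_fasta}: named character vector.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  setNames(as.character(set), names(set))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Format profiles as EMPOP-style variant strings
#'
#' One line per profile: space-separated \code{<position><allele>} tokens
#' sorted by position (e.g. \code{"16093C 16224C"}).  Transition-implied
#' alleles are materialized against \code{reference}.  A profile with no
#' variants yields an empty string (reference-identical).
#'
#' @param profiles List of \code{\link{variant_profile}}s.
#' @param reference Reference segment over the window (defaults to the
#'   packaged synthetic segment).
#' @param path Optional file to write the lines to.
#' @return Named character vector of variant strings, invisibly if
#'   \code{path} is given.
#' @export
write_empop <- function(profiles, reference = hvr1_reference(), path = NULL) {
  lines <- vapply(profiles, function(p) {
    if (!length(p$positions)) return("")
    alleles <- materialize_alleles(p, reference)
    paste0(p$positions, alleles, collapse = " ")
  }, "")
  names(lines) <- vapply(profiles, `[[`, "", "sample_id")
  if (!is.null(path)) {
    writeLines(paste(names(lines), lines, sep = "\t"), path)
    return(invisible(lines))
  }
  lines
}

#' Serialize and restore sample records as JSON
#'
#' @param records List of \code{\link{sample_record}}s.
#' @param path JSON file path.
#' @return \code{read_records} returns a list of sample records equal to
#'   the one serialized.
#' @export
write_records <- function(records, path) {
  payload <- lapply(records, function(r) {
    list(sample_id = r$sample_id, site = r$site, period = r$period,
         window = r$profile$window,
         positions = r$profile$positions,
         alleles = r$profile$alleles,
         rflp = r$rflp,
         reported_hvr1 = r$reported_hvr1,
         reported_rflp = r$reported_rflp)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       na = "null", digits = NA)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload, function(p) {
    rflp <- if (length(p$rflp)) {
      do.call(rbind, lapply(p$rflp, function(o)
        data.frame(enzyme = o$enzyme, position = as.integer(o$position),
                   state = o$state, stringsAsFactors = FALSE)))
    } else NULL
    alleles <- if (length(p$positions)) {
      a <- unlist(lapply(p$alleles, function(x) if (is.null(x)) NA_character_ else x))
      if (is.null(a)) rep(NA_character_, length(p$positions)) else a
    } else character()
    sample_record(p$sample_id, site = p$site %||% NA, period = p$period,
                  profile = variant_profile(p$sample_id,
                                            unlist(p$positions) %||% integer(),
                                            alleles = alleles,
                                            window = unlist(p$window)),
                  rflp = rflp,
                  reported_hvr1 = p$reported_hvr1 %||% NA,
                  reported_rflp = p$reported_rflp %||% NA)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
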