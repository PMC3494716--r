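# evaluate code under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Default haplogroup pools for the admixture generator
#'
#' East pool: the East Eurasian haplogroups observed in the Altai
#' fixture (A, C, D, G2a); West pool: the West Eurasian ones (HV6, J,
#' T1, U5a1, K).  Motifs are taken from the packaged motif table.
#'
#' @param motifs Motif table.
#' @return Named list of two named lists (\code{East}, \code{West}) of
#'   integer motif position vectors.
#' @export
default_haplogroup_pools <- function(motifs = hvr1_motifs()) {
  pick <- function(hgs) setNames(lapply(hgs, function(h) {
    m <- motifs$motif[[match(h, motifs$haplogroup)]]
    if (!length(m)) stop("pool haplogroup '", h, "' has an empty motif")
    m
  }), hgs)
  list(East = pick(c("A", "C", "D", "G2a")),
       West = pick(c("HV6", "J", "T1", "U5a1", "K")))
}

#' Configuration for the synthetic admixed-population generator
#'
#' @param alpha East-ancestry proportion in [0, 1].
#' @param n Number of samples (>= 1).
#' @param seed Integer seed; mandatory, every draw is reproducible.
#' @param pools Haplogroup pools per source, see
#'   \code{\link{default_haplogroup_pools}}.
#' @param private_mutation_rate Expected number of private (non-motif)
#'   variants per lineage (Poisson mean).
#' @param hotspot_positions Positions with elevated mutation rate.
#' @param hotspot_boost Relative rate of hotspot vs ordinary positions
#'   when drawing private/damage variants.
#' @param damage_rate Probability that a sample acquires one spurious
#'   post-mortem singleton transition.
#' @param window HVS-I window.
#' @return Object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(alpha, n, seed,
                              pools = default_haplogroup_pools(),
                              private_mutation_rate = 1,
                              hotspot_positions = NULL,
                              hotspot_boost = 10,
                              damage_rate = 0.02,
                              window = HVR1_WINDOW) {
  if (missing(seed)) stop("seed is mandatory")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (n < 1) stop("n must be >= 1")
  if (private_mutation_rate < 0 || damage_rate < 0 || hotspot_boost <= 0)
    stop("rates must be non-negative")
  if (!length(pools$East) || !length(pools$West))
    stop("both haplogroup pools must be non-empty")
  if (is.null(hotspot_positions))
    hotspot_positions <- read.delim(extdata("hvr1_hotspots.tsv"))$position
  structure(list(alpha = alpha, n = as.integer(n), seed = as.integer(seed),
                 pools = pools,
                 private_mutation_rate = private_mutation_rate,
                 hotspot_positions = as.integer(hotspot_positions),
                 hotspot_boost = hotspot_boost,
                 damage_rate = damage_rate,
                 window = as.integer(window)),
            class = "simulation_config")
}

draw_positions <- function(k, exclude, config) {
  candidates <- setdiff(seq.int(config$window[1], config$window[2]), exclude)
  if (!length(candidates) || k <= 0) return(integer())
  w <- ifelse(candidates %in% config$hotspot_positions,
              config$hotspot_boost, 1)
  sample(candidates, min(k, length(candidates)), prob = w)
}

#' Generate a synthetic admixed dataset with known ground truth
#'
#' Each sample draws its source (East with probability alpha), a
#' haplogroup uniformly from the source pool, the haplogroup's HVS-I
#' motif, a Poisson number of private variants at non-motif positions
#' (hotspot-weighted), and optionally one spurious damage singleton.
#' Fully reproducible given the config seed.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return Object of class \code{"synthetic_dataset"}: list with
#'   \code{records} (sample records) and \code{truth} (data frame:
#'   \code{sample_id}, \code{source}, \code{haplogroup}).
#' @examples
#' sim <- generate_admixed(simulation_config(alpha = 0.5, n = 20, seed = 1))
#' table(sim$truth$source)
#' @export
generate_admixed <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    records <- vector("list", config$n)
    truth <- data.frame(sample_id = sprintf("SIM%04d", seq_len(config$n)),
                        source = NA_character_, haplogroup = NA_character_,
                        stringsAsFactors = FALSE)
    for (i in seq_len(config$n)) {
      source <- if (runif(1) < config$alpha) "East" else "West"
      pool <- config$pools[[source]]
      hg <- sample(names(pool), 1)
      motif <- pool[[hg]]
      priv <- draw_positions(rpois(1, config$private_mutation_rate),
                             motif, config)
      dmg <- if (runif(1) < config$damage_rate)
        draw_positions(1L, c(motif, priv), config) else integer()
      profile <- variant_profile(truth$sample_id[i],
                                 sort(c(motif, priv, dmg)),
                                 window = config$window)
      records[[i]] <- sample_record(truth$sample_id[i], site = "synthetic",
                                    period = "Synthetic", profile = profile)
      truth$source[i] <- source
      truth$haplogroup[i] <- hg
    }
    structure(list(records = records, truth = truth, config = config),
              class = "synthetic_dataset")
  })
}

#' Generate two independent synthetic demes
#'
#' @param config_a,config_b \code{\link{simulation_config}}s (use
#'   different seeds for independent draws).
#' @param labels Population labels for the two demes.
#' @return List with \code{pops} (two \code{population_dataset}s) and
#'   \code{truth} (per-deme truth tables).
#' @export
generate_two_demes <- function(config_a, config_b,
                               labels = c("demeA", "demeB")) {
  sa <- generate_admixed(config_a)
  sb <- generate_admixed(config_b)
  rename <- function(recs, tag) lapply(recs, function(r) {
    r$sample_id <- paste0(tag, "_", r$sample_id)
    r$profile$sample_id <- r$sample_id
    r
  })
  list(pops = list(population_dataset(labels[1], rename(sa$records, labels[1])),
                   population_dataset(labels[2], rename(sb$records, labels[2]))),
       truth = list(sa$truth, sb$truth))
}

#' Estimate the East-Eurasian ancestry fraction of a sample set
#'
#' Runs the full calling pipeline (HVS-I motif call, geographic
#' classification) and reports the East fraction among individuals
#' classified East or West Eurasian.
#'
#' @param records Sample records (or a \code{synthetic_dataset} /
#'   \code{population_dataset}).
#' @param motifs,markers,table Rule tables.
#' @return List with \code{east_fraction}, \code{n_east}, \code{n_west},
#'   \code{n_other}.
#' @export
estimate_east_fraction <- function(records, motifs = hvr1_motifs(),
                                   markers = rflp_markers(),
                                   table = geo_classes()) {
  if (inherits(records, "synthetic_dataset")) records <- records$records
  calls <- call_haplogroups(records, motifs, markers)
  cls <- geo_class(calls$haplogroup, table)
  n_east <- sum(cls == "EastEurasian"); n_west <- sum(cls == "WestEurasian")
  list(east_fraction = n_east / (n_east + n_west),
       n_east = n_east, n_west = n_west,
       n_other = length(cls) - n_east - n_west)
}
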