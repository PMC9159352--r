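#' Simulation configuration for the two-deme planted-sweep model
#'
#' Bundles every parameter of the forward Wright-Fisher simulation, the
#' gestation-length phenotype model and the RNA-seq count generator, so that
#' a single config (plus its mandatory seed) reproduces a complete synthetic
#' study byte-for-byte.
#'
#' The demographic model: one ancestral population of `n_diploid` diploids
#' evolves for `split_generation` generations, is then duplicated into a
#' focal and a reference deme of `n_diploid` each, and the demes evolve
#' independently for the remaining generations. From the split onward the
#' focal deme experiences additive selection at `selected_site`: a parent
#' with derived-allele dosage d is sampled with weight `1 + s * d / 2`.
#'
#' The phenotype model: each focal sow receives `records_per_sow` gestation
#' lengths (days), each `mu_gl_focal - beta * d + N(0, sigma_env)` rounded to
#' whole days, where d is her dosage at the selected site; reference sows get
#' `mu_gl_ref` baseline records with no genetic effect. Defaults are chosen
#' so per-sow means span roughly 110-117 d with most focal means below the
#' porcine norm of 114 d.
#'
#' @param n_diploid diploids per deme.
#' @param n_generations total generations simulated.
#' @param split_generation generation at which the demes split (selection
#'   starts in the focal deme at `sel_start`, default the split).
#' @param n_sites segregating sites simulated.
#' @param region_length region span in bp; positions are drawn uniformly.
#' @param mu per-site, per-gamete mutation probability (0/1 flip).
#' @param rho per-adjacent-site-pair, per-meiosis crossover probability.
#' @param selected_site index of the selected site (default: middle site).
#' @param s additive selection coefficient in the focal deme.
#' @param sel_start first generation with selection (default
#'   `split_generation`).
#' @param sel_init_freq derived-allele frequency at the selected site at
#'   the split, set as an exact count (standing variation at selection
#'   onset); both demes inherit the same state.
#' @param sel_ibd_span bp span on each side of the selected site over which
#'   all carriers share the haplotype of a single founder at the split,
#'   i.e. the standing variant has a single ancestral origin and its
#'   carriers are identical by descent locally, as after a recent partial
#'   sweep. 0 places the allele on unrelated backgrounds (a soft,
#'   multiple-origin variant).
#' @param condition_establishment when selection is active, re-run the
#'   focal deme's post-split phase (from the shared split state, advancing
#'   the RNG stream, so still fully seed-determined) whenever the selected
#'   allele is lost, i.e. condition the sweep on establishment as sweep
#'   simulators conventionally do. Ignored when `s = 0`.
#' @param sel_final_range optional `c(lo, hi)`: additionally condition the
#'   focal deme on the derived allele segregating at a final frequency
#'   inside this range (an ongoing, incomplete sweep, matching a trait that
#'   still segregates in the focal breed). `NULL` disables; ignored when
#'   `s = 0`.
#' @param init_freq optional vector (length `n_sites`) of initial allele
#'   frequencies; default draws each from Uniform(0.1, 0.9).
#' @param n_sample_focal,n_sample_ref diploids sampled (without replacement)
#'   from the final generation of each deme.
#' @param beta gestation-length reduction (days) per derived allele.
#' @param sigma_env residual SD of a single gestation record, days.
#' @param records_per_sow integer range `c(min, max)` of records per sow.
#' @param mu_gl_focal,mu_gl_ref baseline mean gestation length (days).
#' @param n_genes,n_reps_rnaseq,n_breed_genes,n_stage_genes,log2_effect,dispersion
#'   RNA-seq generator: gene count, replicates per breed-by-stage cell,
#'   planted breed-effect and stage-effect gene counts, planted |log2 fold
#'   change|, and negative-binomial dispersion.
#' @param seed mandatory integer seed; all randomness derives from it.
#'
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_diploid = 200, n_generations = 80,
                       split_generation = 30,
                       n_sites = 3000, region_length = 2e6,
                       mu = 1e-6, rho = 5e-4,
                       selected_site = NULL, s = 0.1,
                       sel_start = NULL, sel_init_freq = 0.2,
                       sel_ibd_span = 100000,
                       condition_establishment = TRUE,
                       sel_final_range = c(0.65, 0.9),
                       init_freq = NULL,
                       n_sample_focal = 100, n_sample_ref = 100,
                       beta = 1.5, sigma_env = 1.0,
                       records_per_sow = c(3, 5),
                       mu_gl_focal = 115.5, mu_gl_ref = 115,
                       n_genes = 2000, n_reps_rnaseq = 3,
                       n_breed_genes = 100, n_stage_genes = 100,
                       log2_effect = 3, dispersion = 0.002,
                       seed) {
  if (missing(seed)) stop("`seed` is mandatory: no implicit randomness")
  if (is.null(selected_site)) selected_site <- max(1L, n_sites %/% 2L)
  if (is.null(sel_start)) sel_start <- split_generation
  stopifnot(s >= 0, mu >= 0, mu <= 1, rho >= 0, rho <= 1,
            selected_site >= 1, selected_site <= n_sites,
            n_sample_focal <= n_diploid, n_sample_ref <= n_diploid)
  structure(
    list(n_diploid = as.integer(n_diploid),
         n_generations = as.integer(n_generations),
         split_generation = as.integer(split_generation),
         n_sites = as.integer(n_sites), region_length = as.integer(region_length),
         mu = mu, rho = rho,
         selected_site = as.integer(selected_site), s = s,
         sel_start = as.integer(sel_start), sel_init_freq = sel_init_freq,
         sel_ibd_span = sel_ibd_span,
         condition_establishment = isTRUE(condition_establishment),
         sel_final_range = sel_final_range,
         init_freq = init_freq,
         n_sample_focal = as.integer(n_sample_focal),
         n_sample_ref = as.integer(n_sample_ref),
         beta = beta, sigma_env = sigma_env,
         records_per_sow = as.integer(records_per_sow),
         mu_gl_focal = mu_gl_focal, mu_gl_ref = mu_gl_ref,
         n_genes = as.integer(n_genes), n_reps_rnaseq = as.integer(n_reps_rnaseq),
         n_breed_genes = as.integer(n_breed_genes),
         n_stage_genes = as.integer(n_stage_genes),
         log2_effect = log2_effect, dispersion = dispersion,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# one Wright-Fisher generation: pop is a 2N x L 0/1 matrix, w per-diploid
# sampling weights (length N). Returns the offspring matrix.
wf_generation <- function(pop, w, mu, rho) {
  n_hap <- nrow(pop)
  n_dip <- n_hap %/% 2L
  L <- ncol(pop)
  # each offspring draws two parents (independently, with replacement)
  parents <- sample.int(n_dip, size = n_hap, replace = TRUE, prob = w)
  n_gaps <- L - 1L
  n_cross <- if (n_gaps > 0L && rho > 0) {
    stats::rbinom(n_hap, n_gaps, rho)
  } else {
    integer(n_hap)
  }
  starts <- sample.int(2L, n_hap, replace = TRUE) - 1L
  # every gamete begins as a full copy of its starting parental haplotype;
  # recombinant gametes then swap in the other haplotype beyond crossovers
  nxt <- pop[2L * parents - 1L + starts, , drop = FALSE]
  site0 <- seq_len(L) - 1L
  for (g in which(n_cross > 0L)) {
    bp <- sort.int(sample.int(n_gaps, n_cross[g]))
    sw <- findInterval(site0, bp) %% 2L == 1L
    other <- pop[2L * parents[g] - 1L + (1L - starts[g]), ]
    nxt[g, sw] <- other[sw]
  }
  if (mu > 0) {
    n_mut <- stats::rbinom(1L, n_hap * L, mu)
    if (n_mut > 0L) {
      idx <- sample.int(n_hap * L, n_mut)
      nxt[idx] <- 1L - nxt[idx]
    }
  }
  nxt
}

sel_weights <- function(pop, selected_site, s) {
  n_dip <- nrow(pop) %/% 2L
  d <- pop[seq(1L, 2L * n_dip, by = 2L), selected_site] +
    pop[seq(2L, 2L * n_dip, by = 2L), selected_site]
  1 + s * d / 2
}

#' Forward Wright-Fisher simulation of a planted, trait-linked sweep
#'
#' Runs the two-deme model described in [sim_config()] and returns phased
#' haplotype panels for the sampled focal and reference individuals plus the
#' ground truth needed for recovery scoring.
#'
#' @param config a [sim_config()].
#' @return list with elements `focal`, `ref` (each a [hap_panel()]),
#'   `combined` (both demes in one panel; breeds `"QP"` and `"REF"`), and
#'   `truth` (selected-site position/index, per-deme final derived-allele
#'   frequencies in the deme and in the sample).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  N <- config$n_diploid
  L <- config$n_sites
  positions <- sort.int(sample.int(config$region_length, L))
  p0 <- config$init_freq
  if (is.null(p0)) p0 <- stats::runif(L, 0.1, 0.9)
  p0 <- rep_len(p0, L)
  p0[config$selected_site] <- config$sel_init_freq
  pop <- matrix(stats::rbinom(2L * N * L, 1L, rep(p0, each = 2L * N)), 2L * N, L)

  for (t in seq_len(config$split_generation)) {
    pop <- wf_generation(pop, rep(1, N), config$mu, config$rho)
  }
  # standing variation at selection onset: the selected site is reset to an
  # exact derived-allele count on randomly chosen haplotype rows in the
  # shared pre-split state, so both demes start from the same frequency and
  # the allele cannot be lost to drift before selection begins. With
  # sel_ibd_span > 0 the carriers additionally copy one founder's local
  # haplotype around the selected site: a single-origin standing variant
  # whose carriers are locally identical by descent
  n_carrier <- round(2L * N * config$sel_init_freq)
  carriers <- if (n_carrier > 0L) sample.int(2L * N, n_carrier) else integer(0)
  col <- integer(2L * N)
  col[carriers] <- 1L
  if (length(carriers) > 1L && config$sel_ibd_span > 0L) {
    founder <- carriers[1L]
    span <- which(abs(positions - positions[config$selected_site]) <=
                    config$sel_ibd_span)
    pop[carriers, span] <- rep(pop[founder, span], each = length(carriers))
  }
  pop[, config$selected_site] <- col

  gens_left <- config$n_generations - config$split_generation
  run_deme <- function(start_pop, selected) {
    cur <- start_pop
    for (t in seq_len(gens_left)) {
      gen <- config$split_generation + t
      w <- if (selected && gen > config$sel_start && config$s > 0) {
        sel_weights(cur, config$selected_site, config$s)
      } else {
        rep(1, N)
      }
      cur <- wf_generation(cur, w, config$mu, config$rho)
      if (selected && config$condition_establishment && config$s > 0 &&
          sum(cur[, config$selected_site]) == 0L) {
        return(NULL)  # allele lost: sweep not established
      }
    }
    if (selected && config$s > 0 && !is.null(config$sel_final_range)) {
      p_end <- mean(cur[, config$selected_site])
      if (p_end < config$sel_final_range[1] ||
          p_end > config$sel_final_range[2]) {
        return(NULL)  # outside the conditioned ongoing-sweep window
      }
    }
    cur
  }
  ref <- run_deme(pop, selected = FALSE)
  focal <- NULL
  attempts <- 0L
  while (is.null(focal)) {
    attempts <- attempts + 1L
    if (attempts > 1000L) stop("sweep failed to establish in 1000 attempts")
    focal <- run_deme(pop, selected = TRUE)
  }

  take <- function(pop, n_take, prefix, breed) {
    ids <- sort.int(sample.int(N, n_take))
    rows <- as.vector(rbind(2L * ids - 1L, 2L * ids))
    hap_panel(pop[rows, , drop = FALSE], positions = positions,
              chrom = "1", sample_id = paste0(prefix, seq_len(n_take)),
              breed = breed)
  }
  panel_f <- take(focal, config$n_sample_focal, "QP_", "QP")
  panel_r <- take(ref, config$n_sample_ref, "REF_", "REF")
  sel <- config$selected_site
  truth <- list(
    selected_site = sel,
    selected_pos = positions[sel],
    freq_focal_deme = mean(focal[, sel]),
    freq_ref_deme = mean(ref[, sel]),
    freq_focal_sample = mean(panel_f$haplotypes[, sel]),
    freq_ref_sample = mean(panel_r$haplotypes[, sel])
  )
  list(focal = panel_f, ref = panel_r,
       combined = bind_panels(panel_f, panel_r), truth = truth)
}

#' Stack two panels over the same sites
#'
#' @param x,y [hap_panel()] objects with identical chrom/positions/alleles.
#' @return a [hap_panel()] containing the samples of both.
#' @export
bind_panels <- function(x, y) {
  stopifnot(identical(x$positions, y$positions), identical(x$chrom, y$chrom))
  hap_panel(rbind(x$haplotypes, y$haplotypes), positions = x$positions,
            chrom = x$chrom, ref = x$ref, alt = x$alt,
            sample_id = c(x$sample_id, y$sample_id),
            breed = c(x$breed, y$breed))
}

#' Simulate per-sow gestation-length records
#'
#' Draws the repeated gestation-length records implied by the phenotype model
#' in [sim_config()]: focal-breed sows are penalised `beta` days per derived
#' allele at the selected site; reference sows carry the baseline only.
#' Records are rounded to whole days, as gestation lengths are recorded.
#'
#' @param panel the combined [hap_panel()] from [simulate_panel()].
#' @param truth the `truth` element from [simulate_panel()].
#' @param config the same [sim_config()].
#' @param focal_breed breed label of the focal group in `panel`.
#' @return tibble with one row per sow: `sample_id`, `breed`, `records`
#'   (list-column of day values), `n_records`, `mean_gl`.
#' @export
simulate_phenotypes <- function(panel, truth, config, focal_breed = "QP") {
  set.seed(config$seed + 1L)
  d <- as_dosage(panel)[, truth$selected_site]
  kr <- config$records_per_sow
  purrr::map2_dfr(panel$sample_id, seq_along(panel$sample_id), function(id, i) {
    focal <- panel$breed[i] == focal_breed
    k <- sample(seq(kr[1], kr[2]), 1L)
    base <- if (focal) config$mu_gl_focal - config$beta * d[i] else config$mu_gl_ref
    rec <- round(base + stats::rnorm(k, 0, config$sigma_env))
    tibble::tibble(sample_id = id, breed = panel$breed[i],
                   records = list(rec), n_records = k, mean_gl = mean(rec))
  })
}

#' Simulate RNA-seq count matrices with planted breed and stage effects
#'
#' Generates negative-binomial counts for a 2 breeds x 2 stages x
#' `n_reps_rnaseq` design with three planted gene blocks: breed-effect genes
#' (differential between breeds at both stages), stage-effect genes
#' (differential between late pregnancy and parturition within both breeds),
#' and null genes. This provides inputs with the structure the
#' stage-exclusion set logic assumes.
#'
#' @param config a [sim_config()].
#' @return list: `counts` (gene x sample integer matrix), `samples` (tibble
#'   with `sample`, `breed`, `stage`), `truth` (character vectors
#'   `breed_genes`, `stage_genes`, and tibble `effects` of true log2 fold
#'   changes).
#' @export
simulate_counts <- function(config) {
  set.seed(config$seed + 2L)
  m <- config$n_genes
  reps <- config$n_reps_rnaseq
  genes <- sprintf("GENE%04d", seq_len(m))
  breeds <- rep(c("QP", "LW"), each = 2L * reps)
  stages <- rep(rep(c("PRE", "PAR"), each = reps), times = 2L)
  samples <- tibble::tibble(
    sample = paste0(breeds, "_", stages, "_", rep(seq_len(reps), 4L)),
    breed = breeds, stage = stages
  )
  base <- stats::rlnorm(m, meanlog = 5, sdlog = 1.5)
  idx_breed <- seq_len(config$n_breed_genes)
  idx_stage <- config$n_breed_genes + seq_len(config$n_stage_genes)
  # planted effects sit on solidly expressed genes so that recovery
  # measures the set logic rather than count-limited detection
  n_planted <- config$n_breed_genes + config$n_stage_genes
  base[seq_len(n_planted)] <- stats::rlnorm(n_planted, meanlog = 6, sdlog = 0.8)
  sgn_breed <- sample(c(-1, 1), config$n_breed_genes, replace = TRUE)
  sgn_stage <- sample(c(-1, 1), config$n_stage_genes, replace = TRUE)
  lfc_breed <- numeric(m); lfc_breed[idx_breed] <- sgn_breed * config$log2_effect
  lfc_stage <- numeric(m); lfc_stage[idx_stage] <- sgn_stage * config$log2_effect
  counts <- matrix(0L, m, nrow(samples),
                   dimnames = list(genes, samples$sample))
  size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
  for (j in seq_len(nrow(samples))) {
    lfc <- (samples$breed[j] == "QP") * lfc_breed +
      (samples$stage[j] == "PAR") * lfc_stage
    mu_j <- base * 2^lfc
    counts[, j] <- if (is.finite(size)) {
      stats::rnbinom(m, mu = mu_j, size = size)
    } else {
      stats::rpois(m, mu_j)
    }
  }
  list(counts = counts, samples = samples,
       truth = list(breed_genes = genes[idx_breed],
                    stage_genes = genes[idx_stage],
                    effects = tibble::tibble(gene = genes,
                                             lfc_breed = lfc_breed,
                                             lfc_stage = lfc_stage)))
}
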