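## Synthetic-data generator: emulates a randomized crossover bed-rest study
## (three arms NBR/HBR/HAmb, sampling days -5,-1,3,10,18,21) with a
## Dirichlet-multinomial gut community, DOM absorbance spectra, HPLC peak
## tables, fecal conductivity runs and three explanatory metadata matrices,
## all reproducible from a single seed and carrying ledgers of every planted
## effect.

ARM_LEVELS <- c("NBR", "HBR", "HAmb")
SAMPLING_DAYS <- c(-5L, -1L, 3L, 10L, 18L, 21L)

day_to_week <- function(day) {
  w <- integer(length(day))
  w[day < 0] <- 0L
  w[day == 3] <- 1L
  w[day == 10] <- 2L
  w[day == 18] <- 3L
  w[day == 21] <- 4L
  w
}

#' Configuration for the synthetic crossover-study generator
#'
#' Defaults reproduce the emulated study design: 9 participants crossing over
#' three arms (normoxic bed rest NBR, hypoxic bed rest HBR, hypoxic ambulation
#' HAmb), six sampling days, sequencing depth 105300 +/- 39200 reads per
#' sample, a 2-fold *Bacteroides* enrichment confined to HBR in the final week
#' (days 18 and 21), intestinal-conductivity increases of 67% (HBR) and 32%
#' (NBR) from the first intervention week, and explanatory metadata matrices
#' of widths 109 (chemistry/immune), 12 (experimental design) and 110 (diet).
#'
#' @param n_participants number of participants (>= 2).
#' @param depth_mean,depth_sd mean and SD of per-sample read depth before
#'   truncation at `1000 * scale`.
#' @param bacteroides_fold multiplicative change of the expected *Bacteroides*
#'   relative abundance in effect samples; `1` is the null configuration.
#' @param effect_days,effect_arm where the enrichment is planted.
#' @param iec_week1_increase named per-arm fractional conductivity increase
#'   applied from the first intervention week onward.
#' @param n_meta_vars widths of the chemistry, design and diet metadata
#'   matrices.
#' @param meta_coupled number of community-coupled variables per matrix.
#' @param meta_coupling coupling strength (regression coefficient on the
#'   standardized community gradient) per matrix; `0` decouples a matrix.
#' @param theta Dirichlet concentration mass: larger values give less
#'   compositional overdispersion between replicate samples.
#' @param participant_sigma log-scale SD of the per-participant, per-taxon
#'   concentration tilt (subject effect).
#' @param dropout per-sample probability that a defecation event is missing
#'   (the study collected fewer samples than design slots; no rate is known,
#'   so the default keeps all slots).
#' @param scale down-scaling factor applied to read depth for desk runs.
#' @param seed integer seed from which all child streams are derived.
#' @return an object of class `gutenv_config` (a validated list).
#' @export
generator_config <- function(n_participants = 9,
                             depth_mean = 105300,
                             depth_sd = 39200,
                             bacteroides_fold = 2,
                             effect_days = c(18L, 21L),
                             effect_arm = "HBR",
                             iec_week1_increase = c(HBR = 0.67, NBR = 0.32, HAmb = 0),
                             n_meta_vars = c(chem = 109L, design = 12L, diet = 110L),
                             meta_coupled = c(chem = 8L, design = 4L, diet = 8L),
                             meta_coupling = c(chem = 1, design = 1, diet = 1),
                             theta = 200,
                             participant_sigma = 0.4,
                             dropout = 0,
                             scale = 1,
                             seed = 1L) {
  if (!is.numeric(n_participants) || n_participants < 2)
    stop_gutenv("n_participants must be >= 2")
  if (bacteroides_fold <= 0) stop_gutenv("bacteroides_fold must be positive")
  if (depth_mean <= 0 || depth_sd < 0) stop_gutenv("inconsistent depth parameters")
  if (!effect_arm %in% ARM_LEVELS)
    stop_gutenv("effect_arm must be one of ", paste(ARM_LEVELS, collapse = ", "))
  if (!all(effect_days %in% SAMPLING_DAYS)) stop_gutenv("effect_days outside sampling days")
  if (any(n_meta_vars < 1)) stop_gutenv("metadata matrix widths must be >= 1")
  if (dropout < 0 || dropout >= 1) stop_gutenv("dropout must be in [0, 1)")
  if (scale <= 0) stop_gutenv("scale must be positive")
  structure(list(
    n_participants = as.integer(n_participants), depth_mean = depth_mean,
    depth_sd = depth_sd, bacteroides_fold = bacteroides_fold,
    effect_days = as.integer(effect_days), effect_arm = effect_arm,
    iec_week1_increase = iec_week1_increase, n_meta_vars = n_meta_vars,
    meta_coupled = meta_coupled, meta_coupling = meta_coupling,
    theta = theta, participant_sigma = participant_sigma,
    dropout = dropout, scale = scale, seed = as.integer(seed)),
    class = "gutenv_config")
}

#' Baseline genus-level taxonomy of the simulated community
#'
#' Sixty genera across five phyla with geometric-series expected relative
#' abundances (ratio 0.93), arranged so that Firmicutes plus Bacteroidetes
#' carry over 80% of the community mass, as in healthy adult gut microbiomes.
#' Intermediate ranks are omitted from the synthetic lineage strings.
#'
#' @return data.frame with columns `taxon`, `phylum`, `lineage`, `baseline`
#'   (expected relative abundance; sums to 1).
#' @export
baseline_taxonomy <- function() {
  genera <- c(
    "Bacteroides|Bacteroidetes", "Faecalibacterium|Firmicutes",
    "Blautia|Firmicutes", "Prevotella|Bacteroidetes",
    "Eubacterium|Firmicutes", "Ruminococcus|Firmicutes",
    "Alistipes|Bacteroidetes", "Roseburia|Firmicutes",
    "Coprococcus|Firmicutes", "Bifidobacterium|Actinobacteria",
    "Parabacteroides|Bacteroidetes", "Dorea|Firmicutes",
    "Clostridium|Firmicutes", "Akkermansia|Verrucomicrobia",
    "Escherichia|Proteobacteria", "Lachnospira|Firmicutes",
    "Oscillibacter|Firmicutes", "Dialister|Firmicutes",
    "Anaerostipes|Firmicutes", "Odoribacter|Bacteroidetes",
    "Subdoligranulum|Firmicutes", "Collinsella|Actinobacteria",
    "Phascolarctobacterium|Firmicutes", "Barnesiella|Bacteroidetes",
    "Veillonella|Firmicutes", "Sutterella|Proteobacteria",
    "Lactobacillus|Firmicutes", "Butyricimonas|Bacteroidetes",
    "Streptococcus|Firmicutes", "Eggerthella|Actinobacteria",
    "Enterococcus|Firmicutes", "Paraprevotella|Bacteroidetes",
    "Christensenella|Firmicutes", "Parasutterella|Proteobacteria",
    "Butyrivibrio|Firmicutes", "Adlercreutzia|Actinobacteria",
    "Megasphaera|Firmicutes", "Coprobacter|Bacteroidetes",
    "Acidaminococcus|Firmicutes", "Bilophila|Proteobacteria",
    "Holdemanella|Firmicutes", "Alloprevotella|Bacteroidetes",
    "Romboutsia|Firmicutes", "Gordonibacter|Actinobacteria",
    "Anaerotruncus|Firmicutes", "Victivallis|Verrucomicrobia",
    "Flavonifractor|Firmicutes", "Porphyromonas|Bacteroidetes",
    "Intestinimonas|Firmicutes", "Desulfovibrio|Proteobacteria",
    "Turicibacter|Firmicutes", "Slackia|Actinobacteria",
    "Pseudobutyrivibrio|Firmicutes", "Dysgonomonas|Bacteroidetes",
    "Marvinbryantia|Firmicutes", "Olsenella|Actinobacteria",
    "Luteolibacter|Verrucomicrobia", "Haemophilus|Proteobacteria",
    "Atopobium|Actinobacteria", "Prosthecobacter|Verrucomicrobia")
  parts <- strsplit(genera, "|", fixed = TRUE)
  taxon <- vapply(parts, `[[`, "", 1L)
  phylum <- vapply(parts, `[[`, "", 2L)
  w <- 0.93^(seq_along(taxon) - 1)
  data.frame(taxon = taxon, phylum = phylum,
             lineage = paste(phylum, taxon, sep = ";"),
             baseline = w / sum(w), stringsAsFactors = FALSE)
}

#' Generate the crossover sampling design
#'
#' Every participant contributes all three arms (Latin-square arm ordering
#' derived from the seed) and all six sampling days.
#'
#' @param config a [generator_config()].
#' @return data.frame with columns `sample_id`, `participant_id`, `arm`,
#'   `day`, `week`, `campaign` (the ordinal position of the arm in that
#'   participant's sequence).
#' @export
generate_design <- function(config = generator_config()) {
  stopifnot(inherits(config, "gutenv_config"))
  n <- config$n_participants
  with_seed(child_seed(config$seed, "design"), {
    ## Latin-square arm ordering: each participant gets one of the three
    ## cyclic rotations, rows shuffled by the seed.
    rot <- (seq_len(n) - 1L) %% 3L
    rot <- sample(rot)
    rows <- lapply(seq_len(n), function(i) {
      arms <- ARM_LEVELS[((rot[i] + 0:2) %% 3L) + 1L]
      data.frame(
        participant_id = sprintf("P%02d", i),
        arm = rep(arms, each = length(SAMPLING_DAYS)),
        campaign = rep(1:3, each = length(SAMPLING_DAYS)),
        day = rep(SAMPLING_DAYS, times = 3L),
        stringsAsFactors = FALSE)
    })
    design <- do.call(rbind, rows)
    design$week <- day_to_week(design$day)
    design$sample_id <- sprintf("%s_%s_d%d", design$participant_id, design$arm,
                                design$day)
    if (config$dropout > 0)
      design <- design[runif(nrow(design)) >= config$dropout, , drop = FALSE]
    rownames(design) <- NULL
    design[, c("sample_id", "participant_id", "arm", "day", "week", "campaign")]
  })
}

#' Generate a Dirichlet-multinomial genus count table with a planted effect
#'
#' Per-sample compositions are Dirichlet draws around the baseline genus
#' composition, tilted per participant (log-normal subject effect), with the
#' expected relative abundance of *Bacteroides*-tagged taxa scaled by
#' `bacteroides_fold` in (`effect_arm`, `effect_days`) samples; the remaining
#' taxa are renormalized to the leftover mass so the expected effect-taxon
#' relative-abundance ratio between effect and non-effect samples equals the
#' fold exactly. Counts are multinomial at a truncated-normal read depth.
#'
#' @param design output of [generate_design()].
#' @param config a [generator_config()].
#' @param taxonomy taxonomy table; defaults to [baseline_taxonomy()].
#' @return list with `counts` (taxa x samples integer matrix), `taxonomy`,
#'   and `ledger` (effect taxa, effect samples, fold).
#' @export
generate_counts <- function(design, config = generator_config(),
                            taxonomy = baseline_taxonomy()) {
  stopifnot(inherits(config, "gutenv_config"))
  if (nrow(design) == 0) stop_gutenv("design is empty")
  if (config$bacteroides_fold <= 0) stop_gutenv("bacteroides_fold must be positive")
  n_taxa <- nrow(taxonomy)
  effect_idx <- which(taxonomy$taxon == "Bacteroides")
  effect_samples <- design$sample_id[design$arm == config$effect_arm &
                                       design$day %in% config$effect_days]
  with_seed(child_seed(config$seed, "counts"), {
    participants <- unique(design$participant_id)
    tilt <- matrix(rlnorm(n_taxa * length(participants),
                          sdlog = config$participant_sigma),
                   nrow = n_taxa,
                   dimnames = list(taxonomy$taxon, participants))
    min_depth <- max(1, round(1000 * config$scale))
    mu <- config$depth_mean * config$scale
    sdv <- config$depth_sd * config$scale
    counts <- matrix(0L, nrow = n_taxa, ncol = nrow(design),
                     dimnames = list(taxonomy$taxon, design$sample_id))
    for (j in seq_len(nrow(design))) {
      p <- taxonomy$baseline * tilt[, design$participant_id[j]]
      p <- p / sum(p)
      if (design$sample_id[j] %in% effect_samples &&
          config$bacteroides_fold != 1) {
        p0 <- sum(p[effect_idx])
        target <- min(config$bacteroides_fold * p0, 0.95)
        p[effect_idx] <- p[effect_idx] * target / p0
        p[-effect_idx] <- p[-effect_idx] * (1 - target) / (1 - p0)
      }
      repeat {
        depth <- round(rnorm(1, mu, sdv))
        if (depth >= min_depth) break
      }
      alpha <- config$theta * p
      g <- rgamma(n_taxa, shape = alpha)
      if (sum(g) == 0) g[which.max(alpha)] <- 1
      counts[, j] <- rmultinom(1, size = depth, prob = g / sum(g))[, 1]
    }
    list(counts = counts, taxonomy = taxonomy,
         ledger = list(effect_taxa = taxonomy$taxon[effect_idx],
                       effect_samples = effect_samples,
                       fold = config$bacteroides_fold))
  })
}

#' Generate a random bifurcating phylogeny over the simulated taxa
#'
#' @param taxa character vector of unique taxon labels (>= 2).
#' @param seed integer seed.
#' @return an [ape::rtree()]-style `phylo` object with strictly positive
#'   branch lengths and tip labels equal to `taxa`.
#' @export
generate_tree <- function(taxa, seed = 1L) {
  if (length(taxa) < 2) stop_gutenv("need at least 2 taxa")
  if (anyDuplicated(taxa)) stop_gutenv("duplicate taxon labels")
  with_seed(child_seed(seed, "tree"), {
    tr <- ape::rtree(length(taxa), tip.label = sample(taxa))
    tr$edge.length <- pmax(tr$edge.length, 1e-3)
    tr
  })
}

#' Generate dilution-series DOM absorbance spectra
#'
#' Per sample and dilution (1:10, 1:50, 1:100): absorbance on the 200-800 nm
#' grid (5 nm step) implied by a chromophoric-DOM exponential decay
#' `a0 * exp(-S * (lambda - 275))` plus a Gaussian aromatic band centred at
#' 280 nm, converted to absorbance through the Napierian relation at path
#' length `l`, divided by the dilution factor, with additive instrument
#' noise. TSOC (total soluble organic carbon per g dry matter) is drawn
#' per sample. A ledger records the noise-free undiluted ground-truth
#' indices.
#'
#' @param design output of [generate_design()].
#' @param config a [generator_config()].
#' @param noise_sd additive absorbance noise SD (0 disables noise).
#' @param path_length cuvette/well optical path in cm.
#' @param dilutions dilution factors.
#' @return list with `spectra` (long data.frame: sample_id, dilution,
#'   wavelength_nm, absorbance), `tsoc` (named vector), `path_length`, and
#'   `ledger` (per-sample true generating parameters and true indices).
#' @export
generate_spectra <- function(design, config = generator_config(),
                             noise_sd = 0.002, path_length = 2 / 3,
                             dilutions = c(10L, 50L, 100L)) {
  stopifnot(inherits(config, "gutenv_config"))
  lambda <- seq(200, 800, by = 5)
  with_seed(child_seed(config$seed, "spectra"), {
    n <- nrow(design)
    a0 <- rlnorm(n, log(30), 0.3)
    S <- pmax(rnorm(n, 0.015, 0.002), 0.005)
    band <- rlnorm(n, log(4), 0.4)
    tsoc <- rlnorm(n, log(200), 0.2)
    names(tsoc) <- design$sample_id
    out <- vector("list", n * length(dilutions))
    truth <- vector("list", n)
    k <- 0L
    for (i in seq_len(n)) {
      a_true <- a0[i] * exp(-S[i] * (lambda - 275)) +
        band[i] * exp(-(lambda - 280)^2 / (2 * 15^2))
      A_true <- a_true * path_length / 2.303
      for (d in dilutions) {
        k <- k + 1L
        A <- A_true / d
        if (noise_sd > 0) A <- A + rnorm(length(lambda), 0, noise_sd)
        out[[k]] <- data.frame(sample_id = design$sample_id[i], dilution = d,
                               wavelength_nm = lambda, absorbance = A,
                               stringsAsFactors = FALSE)
      }
      truth[[i]] <- list(a0 = a0[i], S = S[i], band = band[i],
                         tsoc = tsoc[[i]])
    }
    names(truth) <- design$sample_id
    list(spectra = do.call(rbind, out), tsoc = tsoc,
         path_length = path_length, ledger = truth)
  })
}

#' Generate HPLC peak tables for sterol and polyphenol fingerprints
#'
#' Each compound class gets a shared retention-time registry (10-30 peaks)
#' across samples; per-sample areas are log-normal. By default no group
#' effect is planted (the emulated study found none); an optional effect
#' shifts one peak's mean area by a configured factor in the effect samples.
#'
#' @param design output of [generate_design()].
#' @param config a [generator_config()].
#' @param effect optional list(class=, factor=) planting a shift of the first
#'   registry peak of `class` in the config's effect samples.
#' @return list with one long data.frame per class (`sterol`, `polyphenol`):
#'   sample_id, peak_id, retention_min, area; plus `ledger`.
#' @export
generate_peak_tables <- function(design, config = generator_config(),
                                 effect = NULL) {
  stopifnot(inherits(config, "gutenv_config"))
  with_seed(child_seed(config$seed, "peaks"), {
    classes <- c("sterol", "polyphenol")
    effect_samples <- design$sample_id[design$arm == config$effect_arm &
                                         design$day %in% config$effect_days]
    res <- list()
    ledger <- list()
    for (cl in classes) {
      n_peaks <- sample(10:30, 1)
      rt <- sort(runif(n_peaks, 2, 35))
      peak_mean <- rlnorm(n_peaks, log(100), 1)
      tabs <- lapply(seq_len(nrow(design)), function(i) {
        area <- rlnorm(n_peaks, log(peak_mean), 0.4)
        if (!is.null(effect) && effect$class == cl &&
            design$sample_id[i] %in% effect_samples)
          area[1] <- area[1] * effect$factor
        data.frame(sample_id = design$sample_id[i],
                   peak_id = sprintf("%s_pk%02d", cl, seq_len(n_peaks)),
                   retention_min = rt, area = area, stringsAsFactors = FALSE)
      })
      res[[cl]] <- do.call(rbind, tabs)
      ledger[[cl]] <- list(n_peaks = n_peaks,
                           effect = if (!is.null(effect) && effect$class == cl)
                             effect else NULL)
    }
    c(res, list(ledger = ledger))
  })
}

#' Generate per-sample fecal conductivity runs with external KCl standards
#'
#' True intestinal electrical conductivity (IEC) is log-normal around 2 mS/cm
#' per participant; samples from intervention days (week >= 1) in each arm are
#' raised by the per-arm `iec_week1_increase` fraction. Standards are a 1 M
#' KCl solution and its 10-fold dilutions, measured in triplicate and
#' re-measured after every five samples; an optional per-batch gain drift can
#' be planted.
#'
#' @param design output of [generate_design()].
#' @param config a [generator_config()].
#' @param gain instrument gain relating measured to nominal conductivity.
#' @param drift_per_batch fractional gain drift per standards batch.
#' @param noise_sd relative measurement noise.
#' @return list with `samples` (sample_id, reading, batch), `standards`
#'   (level, nominal, measured, replicate, batch), `temperature`, and
#'   `ledger` (true IEC per sample).
#' @export
generate_conductivity <- function(design, config = generator_config(),
                                  gain = 1, drift_per_batch = 0,
                                  noise_sd = 0.01) {
  stopifnot(inherits(config, "gutenv_config"))
  nominal <- c(KCl_1M = 111.9, KCl_0.1M = 12.89, KCl_0.01M = 1.413,
               KCl_0.001M = 0.1469)
  with_seed(child_seed(config$seed, "iec"), {
    participants <- unique(design$participant_id)
    base <- rlnorm(length(participants), log(2), 0.15)
    names(base) <- participants
    inc <- config$iec_week1_increase[design$arm]
    inc[is.na(inc)] <- 0
    truth <- base[design$participant_id] * (1 + ifelse(design$week >= 1, inc, 0)) *
      rlnorm(nrow(design), 0, 0.05)
    names(truth) <- design$sample_id
    batch <- ceiling(seq_len(nrow(design)) / 5)
    readings <- gain * (1 + drift_per_batch * (batch - 1)) * truth *
      rlnorm(nrow(design), 0, noise_sd)
    n_batches <- max(batch)
    std <- expand.grid(level = names(nominal), replicate = 1:3,
                       batch = seq_len(n_batches), stringsAsFactors = FALSE)
    std$nominal <- nominal[std$level]
    std$measured <- gain * (1 + drift_per_batch * (std$batch - 1)) *
      std$nominal * rlnorm(nrow(std), 0, noise_sd)
    list(samples = data.frame(sample_id = design$sample_id, reading = readings,
                              batch = batch, stringsAsFactors = FALSE),
         standards = std[, c("level", "nominal", "measured", "replicate", "batch")],
         temperature = 28,
         ledger = list(true_iec = truth, gain = gain,
                       drift_per_batch = drift_per_batch))
  })
}

#' Generate the three explanatory metadata matrices
#'
#' Three samples x variables matrices of the configured widths (defaults 109,
#' 12, 110). In each matrix, `meta_coupled` variables are linearly coupled
#' (coefficient `meta_coupling`, plus unit Gaussian noise) to the planted
#' community gradient; all remaining variables are pure noise. The design
#' matrix additionally carries the deterministic design encodings day, week
#' and arm indicators as its first columns.
#'
#' @param design output of [generate_design()].
#' @param config a [generator_config()].
#' @param gradient optional numeric per-sample community gradient (e.g. the
#'   standardized log effect-taxon relative abundance from a generated count
#'   table); defaults to the standardized indicator of effect samples.
#' @return list with matrices `chem`, `design`, `diet` (rows = samples) and a
#'   `ledger` naming the coupled variables and their coefficients.
#' @export
generate_metadata_matrices <- function(design, config = generator_config(),
                                       gradient = NULL) {
  stopifnot(inherits(config, "gutenv_config"))
  n <- nrow(design)
  if (is.null(gradient)) {
    gradient <- as.numeric(design$arm == config$effect_arm &
                             design$day %in% config$effect_days)
  }
  if (length(gradient) != n) stop_gutenv("gradient length must match design rows")
  g <- if (sd(gradient) > 0) (gradient - mean(gradient)) / sd(gradient)
       else gradient * 0
  with_seed(child_seed(config$seed, "metadata"), {
    ledger <- list()
    mats <- list()
    for (nm in c("chem", "design", "diet")) {
      width <- config$n_meta_vars[[nm]]
      fixed <- NULL
      if (nm == "design") {
        fixed <- cbind(day = design$day, week = design$week,
                       arm_HBR = as.numeric(design$arm == "HBR"),
                       arm_HAmb = as.numeric(design$arm == "HAmb"))
        fixed <- fixed[, seq_len(min(ncol(fixed), width)), drop = FALSE]
      }
      n_free <- width - if (is.null(fixed)) 0L else ncol(fixed)
      m <- matrix(rnorm(n * n_free), nrow = n)
      colnames(m) <- sprintf("%s_v%03d", nm, seq_len(n_free))
      k <- min(config$meta_coupled[[nm]], n_free)
      beta <- config$meta_coupling[[nm]]
      if (k > 0 && beta != 0)
        m[, seq_len(k)] <- m[, seq_len(k)] + beta * g
      mat <- if (is.null(fixed)) m else cbind(fixed, m)
      rownames(mat) <- design$sample_id
      mats[[nm]] <- mat
      ledger[[nm]] <- list(
        coupled = if (k > 0 && beta != 0) colnames(m)[seq_len(k)] else character(),
        coefficient = beta)
    }
    c(mats, list(ledger = ledger))
  })
}

#' Generate a complete synthetic study dataset
#'
#' Runs every generator stage from one config, coupling the metadata matrices
#' to the realized community gradient (standardized log effect-taxon relative
#' abundance).
#'
#' @param config a [generator_config()].
#' @param dir optional directory; when given, all outputs are written as
#'   tab-separated text plus `tree.nwk` and `ledger.json`.
#' @return list of class `gutenv_dataset` with elements `design`, `counts`,
#'   `taxonomy`, `tree`, `spectra`, `tsoc`, `path_length`, `peaks`,
#'   `conductivity`, `meta`, `ledger`.
#' @export
generate_dataset <- function(config = generator_config(), dir = NULL) {
  design <- generate_design(config)
  cts <- generate_counts(design, config)
  tree <- generate_tree(rownames(cts$counts), seed = config$seed)
  spec <- generate_spectra(design, config)
  peaks <- generate_peak_tables(design, config)
  cond <- generate_conductivity(design, config)
  rel <- colSums(cts$counts[cts$ledger$effect_taxa, , drop = FALSE]) /
    pmax(colSums(cts$counts), 1)
  gradient <- log(rel + 1e-6)
  meta <- generate_metadata_matrices(design, config, gradient = gradient)
  ds <- structure(list(
    design = design, counts = cts$counts, taxonomy = cts$taxonomy, tree = tree,
    spectra = spec$spectra, tsoc = spec$tsoc, path_length = spec$path_length,
    peaks = peaks[c("sterol", "polyphenol")], conductivity = cond,
    meta = meta[c("chem", "design", "diet")],
    ledger = list(counts = cts$ledger, spectra = spec$ledger,
                  peaks = peaks$ledger, conductivity = cond$ledger,
                  metadata = meta$ledger, config = unclass(config))),
    class = "gutenv_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' Write a generated dataset as plain-text files
#'
#' Writes `counts.tsv` (first column the lineage string, then one integer
#' column per sample), `design.tsv`, `tree.nwk`, `spectra.tsv` (long format),
#' `peaks_sterol.tsv`, `peaks_polyphenol.tsv`, `iec_run.tsv` +
#' `iec_standards.tsv`, `meta_{chem,design,diet}.tsv`, `tsoc.tsv` and
#' `ledger.json`.
#'
#' @param ds a `gutenv_dataset`.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "gutenv_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) {
    write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
    f
  }
  files <- character()
  cnt <- data.frame(lineage = ds$taxonomy$lineage[match(rownames(ds$counts),
                                                        ds$taxonomy$taxon)],
                    ds$counts, check.names = FALSE)
  files <- c(files, tsv(cnt, "counts.tsv"), tsv(ds$design, "design.tsv"))
  ape::write.tree(ds$tree, file.path(dir, "tree.nwk"))
  files <- c(files, "tree.nwk", tsv(ds$spectra, "spectra.tsv"))
  files <- c(files, tsv(data.frame(sample_id = names(ds$tsoc), tsoc = ds$tsoc),
                        "tsoc.tsv"))
  files <- c(files, tsv(ds$peaks$sterol, "peaks_sterol.tsv"),
             tsv(ds$peaks$polyphenol, "peaks_polyphenol.tsv"),
             tsv(ds$conductivity$samples, "iec_run.tsv"),
             tsv(ds$conductivity$standards, "iec_standards.tsv"))
  for (nm in names(ds$meta)) {
    files <- c(files, tsv(data.frame(sample_id = rownames(ds$meta[[nm]]),
                                     ds$meta[[nm]], check.names = FALSE),
                          sprintf("meta_%s.tsv", nm)))
  }
  ledger <- ds$ledger
  ledger$spectra <- NULL  # per-sample generating params stay in-memory only
  jsonlite::write_json(ledger, file.path(dir, "ledger.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(c(files, "ledger.json"))
}

#' Read a count table written by [write_dataset()]
#'
#' @param path path to `counts.tsv`.
#' @return list with `counts` matrix and `taxonomy` data.frame (taxon =
#'   terminal lineage field, phylum = first field).
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  lineage <- df[[1]]
  parts <- strsplit(lineage, ";", fixed = TRUE)
  taxon <- vapply(parts, function(p) p[length(p)], "")
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- taxon
  list(counts = counts,
       taxonomy = data.frame(taxon = taxon,
                             phylum = vapply(parts, `[[`, "", 1L),
                             lineage = lineage, stringsAsFactors = FALSE))
}
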