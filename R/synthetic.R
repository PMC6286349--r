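#' Reference table of common gut genera
#'
#' Forty bacterial genera typical of the child gut microbiome, with their
#' family/order/class/phylum lineage, used to label synthetic OTUs.
#'
#' @return data frame: genus, family, order, class, phylum.
#' @export
gut_genus_reference <- function() {
  raw <- c(
    "Bacteroides|Bacteroidaceae|Bacteroidales|Bacteroidia|Bacteroidetes",
    "Prevotella|Prevotellaceae|Bacteroidales|Bacteroidia|Bacteroidetes",
    "Parabacteroides|Porphyromonadaceae|Bacteroidales|Bacteroidia|Bacteroidetes",
    "Alistipes|Rikenellaceae|Bacteroidales|Bacteroidia|Bacteroidetes",
    "Odoribacter|Odoribacteraceae|Bacteroidales|Bacteroidia|Bacteroidetes",
    "Butyricimonas|Odoribacteraceae|Bacteroidales|Bacteroidia|Bacteroidetes",
    "Faecalibacterium|Ruminococcaceae|Clostridiales|Clostridia|Firmicutes",
    "Ruminococcus|Ruminococcaceae|Clostridiales|Clostridia|Firmicutes",
    "Oscillospira|Ruminococcaceae|Clostridiales|Clostridia|Firmicutes",
    "Blautia|Lachnospiraceae|Clostridiales|Clostridia|Firmicutes",
    "Dorea|Lachnospiraceae|Clostridiales|Clostridia|Firmicutes",
    "Roseburia|Lachnospiraceae|Clostridiales|Clostridia|Firmicutes",
    "Coprococcus|Lachnospiraceae|Clostridiales|Clostridia|Firmicutes",
    "Lachnospira|Lachnospiraceae|Clostridiales|Clostridia|Firmicutes",
    "Anaerostipes|Lachnospiraceae|Clostridiales|Clostridia|Firmicutes",
    "Clostridium|Clostridiaceae|Clostridiales|Clostridia|Firmicutes",
    "Eubacterium|Eubacteriaceae|Clostridiales|Clostridia|Firmicutes",
    "Christensenella|Christensenellaceae|Clostridiales|Clostridia|Firmicutes",
    "Phascolarctobacterium|Veillonellaceae|Clostridiales|Clostridia|Firmicutes",
    "Dialister|Veillonellaceae|Clostridiales|Clostridia|Firmicutes",
    "Veillonella|Veillonellaceae|Clostridiales|Clostridia|Firmicutes",
    "Megasphaera|Veillonellaceae|Clostridiales|Clostridia|Firmicutes",
    "Catenibacterium|Erysipelotrichaceae|Erysipelotrichales|Erysipelotrichi|Firmicutes",
    "Holdemania|Erysipelotrichaceae|Erysipelotrichales|Erysipelotrichi|Firmicutes",
    "Turicibacter|Turicibacteraceae|Turicibacterales|Bacilli|Firmicutes",
    "Streptococcus|Streptococcaceae|Lactobacillales|Bacilli|Firmicutes",
    "Lactococcus|Streptococcaceae|Lactobacillales|Bacilli|Firmicutes",
    "Lactobacillus|Lactobacillaceae|Lactobacillales|Bacilli|Firmicutes",
    "Enterococcus|Enterococcaceae|Lactobacillales|Bacilli|Firmicutes",
    "Bifidobacterium|Bifidobacteriaceae|Bifidobacteriales|Actinobacteria|Actinobacteria",
    "Collinsella|Coriobacteriaceae|Coriobacteriales|Coriobacteriia|Actinobacteria",
    "Slackia|Coriobacteriaceae|Coriobacteriales|Coriobacteriia|Actinobacteria",
    "Sutterella|Alcaligenaceae|Burkholderiales|Betaproteobacteria|Proteobacteria",
    "Bilophila|Desulfovibrionaceae|Desulfovibrionales|Deltaproteobacteria|Proteobacteria",
    "Desulfovibrio|Desulfovibrionaceae|Desulfovibrionales|Deltaproteobacteria|Proteobacteria",
    "Escherichia|Enterobacteriaceae|Enterobacteriales|Gammaproteobacteria|Proteobacteria",
    "Klebsiella|Enterobacteriaceae|Enterobacteriales|Gammaproteobacteria|Proteobacteria",
    "Haemophilus|Pasteurellaceae|Pasteurellales|Gammaproteobacteria|Proteobacteria",
    "Akkermansia|Verrucomicrobiaceae|Verrucomicrobiales|Verrucomicrobiae|Verrucomicrobia",
    "Methanobrevibacter|Methanobacteriaceae|Methanobacteriales|Methanobacteria|Euryarchaeota")
  parts <- do.call(rbind, strsplit(raw, "|", fixed = TRUE))
  data.frame(genus = parts[, 1], family = parts[, 2], order = parts[, 3],
             class = parts[, 4], phylum = parts[, 5], stringsAsFactors = FALSE)
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a two-time-point
#' prospective cohort (70 subjects, 140 samples by default) whose gut
#' communities occupy a small number of latent "steady states" with a
#' biodiversity gradient, whose diets fall into latent groups coupled to
#' the community state, and whose inflammatory markers track the community
#' gradient.
#'
#' @param n_subjects number of subjects (default 70).
#' @param n_timepoints samples per subject (default 2; labelled T1/T3).
#' @param n_otus number of OTUs (default 300).
#' @param n_genera number of genera the OTUs map to (default 40).
#' @param n_states latent community states (default 4).
#' @param n_diet_groups latent dietary groups (default 5).
#' @param reads_per_sample mean library size (default 5000; drawn
#'   lognormally with coefficient of variation `library_size_cv`).
#' @param state_diversity_gradient per-state Dirichlet shape scalars,
#'   strictly positive; larger values give more even genus profiles and
#'   hence higher expected Shannon diversity (default `c(1, 2, 4, 8)`).
#' @param state_persistence probability that a subject's second sample
#'   stays in the same state (default 0.75).
#' @param dirichlet_concentration total concentration of the per-sample
#'   Dirichlet draw around the state profile; lower values give more
#'   overdispersion (default 100).
#' @param n_cags latent co-abundance groups of genera (default 4).
#' @param cag_sd log-scale s.d. of the shared per-sample CAG factors that
#'   induce within-CAG genus correlations (default 0.4).
#' @param subject_sd log-scale s.d. of per-subject genus effects shared by a
#'   subject's samples, giving individuals a persistent microbial signature
#'   so that a minority of subjects cluster by individual rather than by
#'   state (default 0.8).
#' @param diet_confusion `n_states x n_diet_groups` row-stochastic matrix
#'   giving P(diet group | state); `NULL` builds one that places
#'   `diet_state_coupling` mass on the mapped diet group
#'   `((state - 1) %% n_diet_groups) + 1` and spreads the rest evenly.
#' @param diet_state_coupling coupling mass for the default confusion
#'   matrix (default 0.6).
#' @param diet_sharpness separation of the diet templates along the food
#'   healthiness gradient (default 1.2); 0 spaces all templates at the same
#'   position.
#' @param diet_idiosyncrasy log-scale s.d. of template-specific per-food
#'   deviations from the gradient (default 0.15); with sharpness and
#'   idiosyncrasy both 0 every template is identical.
#' @param ffq_noise_sd log-scale s.d. of the per-food consumption noise
#'   (default 0.35).
#' @param inflammation_effect slope of the inflammatory markers on the
#'   latent community gradient score, in marker-scale units per gradient
#'   s.d. (default 1).
#' @param marker_noise_sd marker noise, in units of each marker's scale
#'   (default 1).
#' @param unclassified_frac fraction of OTUs left unclassified at genus
#'   rank (default 0.05).
#' @param library_size_cv coefficient of variation of library sizes
#'   (default 0.395, matching an sd/mean of roughly 22000/56000).
#' @param seed integer random seed; every generator is a pure function of
#'   (config, seed).
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 70, n_timepoints = 2, n_otus = 300,
                             n_genera = 40, n_states = 4, n_diet_groups = 5,
                             reads_per_sample = 5000,
                             state_diversity_gradient = NULL,
                             state_persistence = 0.75,
                             dirichlet_concentration = 100,
                             n_cags = 4, cag_sd = 0.4, subject_sd = 0.8,
                             diet_confusion = NULL, diet_state_coupling = 0.6,
                             diet_sharpness = 1.2, diet_idiosyncrasy = 0.15,
                             ffq_noise_sd = 0.35,
                             inflammation_effect = 1, marker_noise_sd = 1,
                             unclassified_frac = 0.05,
                             library_size_cv = 0.395, seed = 1L) {
  if (!is_count(n_subjects) || !is_count(n_timepoints) || !is_count(n_otus) ||
      !is_count(n_genera) || !is_count(n_states) || !is_count(n_diet_groups))
    stop_invalid("counts must be positive integers")
  if (n_states < 2) stop_invalid("n_states must be at least 2")
  if (n_diet_groups < 2) stop_invalid("n_diet_groups must be at least 2")
  if (reads_per_sample <= 0) stop_invalid("reads_per_sample must be positive")
  if (is.null(state_diversity_gradient))
    state_diversity_gradient <- 2^(seq_len(n_states) - 1)
  if (length(state_diversity_gradient) != n_states ||
      any(state_diversity_gradient <= 0))
    stop_invalid("state_diversity_gradient needs exactly n_states strictly positive entries")
  if (state_persistence < 0 || state_persistence > 1)
    stop_invalid("state_persistence must lie in [0, 1]")
  if (!is.null(diet_confusion)) {
    diet_confusion <- as.matrix(diet_confusion)
    if (!all(dim(diet_confusion) == c(n_states, n_diet_groups)) ||
        any(diet_confusion < 0) ||
        any(abs(rowSums(diet_confusion) - 1) > 1e-9))
      stop_invalid("diet_confusion must be a row-stochastic n_states x n_diet_groups matrix")
  }
  structure(list(
    n_subjects = n_subjects, n_timepoints = n_timepoints, n_otus = n_otus,
    n_genera = n_genera, n_states = n_states, n_diet_groups = n_diet_groups,
    reads_per_sample = reads_per_sample,
    state_diversity_gradient = state_diversity_gradient,
    state_persistence = state_persistence,
    dirichlet_concentration = dirichlet_concentration,
    n_cags = n_cags, cag_sd = cag_sd, subject_sd = subject_sd,
    diet_confusion = diet_confusion,
    diet_state_coupling = diet_state_coupling,
    diet_sharpness = diet_sharpness,
    diet_idiosyncrasy = diet_idiosyncrasy, ffq_noise_sd = ffq_noise_sd,
    inflammation_effect = inflammation_effect,
    marker_noise_sd = marker_noise_sd,
    unclassified_frac = unclassified_frac,
    library_size_cv = library_size_cv, seed = as.integer(seed)
  ), class = "synthetic_config")
}

sample_ids_for <- function(config) {
  subjects <- sprintf("S%03d", seq_len(config$n_subjects))
  tp <- if (config$n_timepoints == 2) c("T1", "T3")
        else paste0("T", seq_len(config$n_timepoints))
  list(subjects = subjects, timepoints = tp,
       samples = as.vector(t(outer(subjects, tp, paste, sep = "_"))),
       subject_of = rep(subjects, each = config$n_timepoints),
       timepoint_of = rep(tp, times = config$n_subjects))
}

#' Generate a random rooted phylogeny over synthetic OTUs
#'
#' @param n_otus number of tips (>= 2).
#' @param seed integer seed; the same seed reproduces the tree exactly.
#' @return a rooted binary `phylo` with tips `OTU0001..`, all branch
#'   lengths strictly positive.
#' @export
generate_tree <- function(n_otus, seed = 1L) {
  if (!is_count(n_otus, min = 2)) stop_invalid("n_otus must be an integer >= 2")
  set.seed(seed)
  tree <- ape::rtree(n_otus, tip.label = sprintf("OTU%04d", seq_len(n_otus)))
  tree$edge.length <- pmax(tree$edge.length, 1e-6)
  tree
}

## latent state sequence per subject: stay with prob state_persistence,
## otherwise jump uniformly to another state
draw_subject_states <- function(config) {
  t1 <- sample.int(config$n_states, config$n_subjects, replace = TRUE)
  states <- matrix(0L, config$n_subjects, config$n_timepoints)
  states[, 1] <- t1
  if (config$n_timepoints > 1) {
    for (tp in 2:config$n_timepoints) {
      stay <- stats::runif(config$n_subjects) < config$state_persistence
      jump <- vapply(states[, tp - 1], function(s)
        sample(setdiff(seq_len(config$n_states), s), 1), integer(1))
      states[, tp] <- ifelse(stay, states[, tp - 1], jump)
    }
  }
  states
}

#' Generate a synthetic OTU count table with known state labels
#'
#' Each latent state has a genus-level profile drawn with a state-specific
#' Dirichlet shape (the diversity gradient); genus mass is split over that
#' genus's OTUs with fixed weights. Per sample, counts follow a
#' Dirichlet-multinomial around the state profile (concentration
#' `dirichlet_concentration`, emulating 16S overdispersion), modulated by
#' shared lognormal factors per co-abundance group, with lognormal library
#' sizes around `reads_per_sample`.
#'
#' @param config a [synthetic_config].
#' @return list: `table` (an [otu_table]), `truth` (list with per-sample
#'   `state` ("S1".."Sk"), per-genus `cag`, `subject_map`, `timepoint`,
#'   `state_index`).
#' @export
generate_otu_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  ids <- sample_ids_for(config)
  ref <- gut_genus_reference()
  genera <- if (config$n_genera <= nrow(ref)) ref$genus[seq_len(config$n_genera)]
            else c(ref$genus, sprintf("Genus%02d", seq_len(config$n_genera - nrow(ref))))
  otu_ids <- sprintf("OTU%04d", seq_len(config$n_otus))
  otu_genus <- sample(rep_len(seq_len(config$n_genera), config$n_otus))
  within_weight <- numeric(config$n_otus)
  for (g in seq_len(config$n_genera)) {
    idx <- which(otu_genus == g)
    w <- stats::rgamma(length(idx), 1)
    within_weight[idx] <- w / sum(w)
  }
  cag_of_genus <- sample(rep_len(seq_len(config$n_cags), config$n_genera))
  # state genus profiles: evenness governed by the diversity gradient
  state_profiles <- sapply(seq_len(config$n_states), function(s) {
    w <- stats::rgamma(config$n_genera, shape = config$state_diversity_gradient[s])
    w <- pmax(w, 1e-12)
    w / sum(w)
  })
  subject_states <- draw_subject_states(config)
  state_of_sample <- as.vector(t(subject_states))
  sigma <- sqrt(log(1 + config$library_size_cv^2))
  n_samples <- length(ids$samples)
  libsize <- round(stats::rlnorm(n_samples,
                                 log(config$reads_per_sample) - sigma^2 / 2,
                                 sigma))
  libsize <- pmax(libsize, 100)
  counts <- matrix(0L, n_samples, config$n_otus,
                   dimnames = list(ids$samples, otu_ids))
  alpha_base <- state_profiles[otu_genus, , drop = FALSE] * within_weight
  # persistent per-subject genus signature shared by a subject's samples
  subject_factor <- matrix(exp(stats::rnorm(config$n_subjects * config$n_genera,
                                            0, config$subject_sd)),
                           config$n_subjects, config$n_genera)
  subject_idx <- match(ids$subject_of, ids$subjects)
  for (i in seq_len(n_samples)) {
    alpha <- config$dirichlet_concentration * alpha_base[, state_of_sample[i]]
    x <- stats::rgamma(config$n_otus, shape = alpha)
    cag_factor <- exp(stats::rnorm(config$n_cags, 0, config$cag_sd))
    x <- x * cag_factor[cag_of_genus[otu_genus]] *
      subject_factor[subject_idx[i], otu_genus]
    if (sum(x) <= 0) x[which.max(alpha)] <- 1
    counts[i, ] <- stats::rmultinom(1, libsize[i], x / sum(x))
  }
  unclassified <- stats::runif(config$n_otus) < config$unclassified_frac
  lineage <- vapply(seq_len(config$n_otus), function(j) {
    g <- genera[otu_genus[j]]
    row <- ref[match(g, ref$genus), ]
    if (is.na(row$genus))  # synthetic filler genus
      row <- list(phylum = "Firmicutes", class = "Clostridia",
                  order = "Clostridiales", family = "Lachnospiraceae", genus = g)
    if (unclassified[j])
      sprintf("k__Bacteria;p__%s;c__%s;o__%s;f__%s;g__", row$phylum, row$class,
              row$order, row$family)
    else
      sprintf("k__Bacteria;p__%s;c__%s;o__%s;f__%s;g__%s", row$phylum,
              row$class, row$order, row$family, row$genus)
  }, character(1))
  truth <- list(
    state = stats::setNames(paste0("S", state_of_sample), ids$samples),
    state_index = stats::setNames(state_of_sample, ids$samples),
    cag = stats::setNames(paste0("G", cag_of_genus), genera),
    subject_map = stats::setNames(ids$subject_of, ids$samples),
    timepoint = stats::setNames(ids$timepoint_of, ids$samples)
  )
  list(table = otu_table(counts, stats::setNames(lineage, otu_ids)),
       truth = truth)
}

## diet templates along a single "healthiness" gradient so that the first
## correspondence-analysis axis carries the diet signal
diet_templates <- function(config, foods) {
  z <- as.numeric(scale(foods$health_value))
  positions <- seq(-1, 1, length.out = config$n_diet_groups)
  idio <- matrix(stats::rnorm(nrow(foods) * config$n_diet_groups, 0,
                              config$diet_idiosyncrasy),
                 nrow(foods), config$n_diet_groups)
  templates <- sapply(seq_len(config$n_diet_groups), function(k) {
    w <- exp(config$diet_sharpness * positions[k] * z + idio[, k])
    15 * w / sum(w)   # ~15 consumption events per day
  })
  rownames(templates) <- foods$food
  templates
}

default_diet_confusion <- function(config) {
  if (!is.null(config$diet_confusion)) return(config$diet_confusion)
  P <- matrix((1 - config$diet_state_coupling) / (config$n_diet_groups - 1),
              config$n_states, config$n_diet_groups)
  for (s in seq_len(config$n_states))
    P[s, ((s - 1) %% config$n_diet_groups) + 1] <- config$diet_state_coupling
  P
}

#' Generate a synthetic FFQ table with known diet-group labels
#'
#' Diet-group templates sit at distinct positions along a food-healthiness
#' gradient (so the dominant correspondence-analysis axis reflects diet);
#' each sample draws its diet group from its community state through the
#' configured confusion matrix and multiplies the template with lognormal
#' per-food noise.
#'
#' @param config a [synthetic_config].
#' @param truth_states per-sample state labels (`"S1"`..; from
#'   [generate_otu_table]).
#' @return list: `ffq` (an [ffq_table] over the 50 packaged foods),
#'   `truth_diet` (per-sample `"D1"`.. labels).
#' @export
generate_ffq <- function(config, truth_states) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  foods <- food_reference()
  templates <- diet_templates(config, foods)
  P <- default_diet_confusion(config)
  state_idx <- as.integer(sub("^S", "", truth_states))
  if (anyNA(state_idx)) stop_invalid("truth_states must look like 'S1', 'S2', ...")
  n <- length(truth_states)
  diet <- vapply(state_idx, function(s)
    sample.int(config$n_diet_groups, 1, prob = P[s, ]), integer(1))
  noise <- matrix(stats::rlnorm(n * nrow(foods), 0, config$ffq_noise_sd),
                  n, nrow(foods))
  vals <- t(templates[, diet, drop = FALSE]) * noise
  dimnames(vals) <- list(names(truth_states), foods$food)
  list(ffq = ffq_table(vals, foods = foods),
       truth_diet = stats::setNames(paste0("D", diet), names(truth_states)))
}

## inflammatory/clinical marker reference: baseline and per-unit scale
marker_reference <- function() {
  data.frame(
    marker = c("crp", "il6", "il8", "il15", "tnf_alpha", "ip10",
               "triglycerides", "diastolic_bp", "glucose"),
    baseline = c(0.6, 2.0, 6.0, 2.5, 8.0, 150, 70, 62, 85),
    scale = c(0.5, 1.0, 2.5, 1.0, 3.0, 40, 20, 6, 8),
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic per-sample metadata with inflammation coupled to the
#' community gradient
#'
#' Ages, gender, activity and education scores, weight status and a panel
#' of inflammatory/clinical markers. Each marker equals its baseline plus
#' `inflammation_effect` times the latent state gradient score (standardized
#' across states, higher in low-diversity states) times the marker's scale,
#' plus Gaussian noise. Excessive weight gain at the second time point is
#' enriched in subjects whose final state has low diversity.
#'
#' @param config a [synthetic_config].
#' @param table the generated [otu_table] (sample order is taken from it).
#' @param truth_states per-sample state labels.
#' @return data frame, one row per sample: sample, subject, timepoint, age,
#'   gender, weight_status, group (T1_N/T1_O/T3_N/T3_O for two-time-point
#'   designs), mvpa_score, education_score, and the marker columns.
#' @export
generate_metadata <- function(config, table, truth_states) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 2L)
  ids <- sample_ids_for(config)
  samples <- sample_ids(table)
  stopifnot(identical(samples, ids$samples))
  state_idx <- as.integer(sub("^S", "", truth_states[samples]))
  # gradient score: standardized rank of decreasing diversity, so
  # low-diversity states score high (the inflammation direction)
  rk <- rank(-config$state_diversity_gradient)
  gscore_by_state <- as.numeric(scale(rk))
  gscore <- gscore_by_state[state_idx]
  age_t1 <- round(stats::runif(config$n_subjects, 6, 9), 1)
  age <- age_t1[match(ids$subject_of, ids$subjects)] +
    4 * (match(ids$timepoint_of, ids$timepoints) - 1) /
      max(1, config$n_timepoints - 1) *
      (config$n_timepoints > 1)
  gender <- sample(c("female", "male"), config$n_subjects, replace = TRUE)
  last_tp <- ids$timepoints[config$n_timepoints]
  final_gscore <- gscore[ids$timepoint_of == last_tp][
    match(ids$subjects, ids$subject_of[ids$timepoint_of == last_tp])]
  develops <- stats::runif(config$n_subjects) < stats::plogis(1.2 * final_gscore)
  weight_status <- ifelse(ids$timepoint_of == last_tp &
                            develops[match(ids$subject_of, ids$subjects)],
                          "obese", "normal")
  group <- paste0(ids$timepoint_of, "_",
                  ifelse(develops[match(ids$subject_of, ids$subjects)], "O", "N"))
  mvpa <- round(stats::rnorm(length(samples), 50, 15), 1)
  education <- round(stats::rnorm(config$n_subjects, 0, 1), 2)[
    match(ids$subject_of, ids$subjects)]
  mk <- marker_reference()
  markers <- sapply(seq_len(nrow(mk)), function(m) {
    round(pmax(0, mk$baseline[m] +
                 config$inflammation_effect * mk$scale[m] * gscore +
                 stats::rnorm(length(samples), 0,
                              config$marker_noise_sd * mk$scale[m])), 3)
  })
  colnames(markers) <- mk$marker
  data.frame(sample = samples, subject = ids$subject_of,
             timepoint = ids$timepoint_of, age = age,
             gender = gender[match(ids$subject_of, ids$subjects)],
             weight_status = weight_status, group = group,
             mvpa_score = mvpa, education_score = education,
             markers, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic cohort
#'
#' Bundles [generate_tree], [generate_otu_table], [generate_ffq] and
#' [generate_metadata] into one object with ground-truth labels, suitable
#' for exercising the whole analysis pipeline.
#'
#' @param config a [synthetic_config] (default configuration if omitted).
#' @return object of class `synthetic_cohort`: `otu_table`, `tree`, `ffq`,
#'   `metadata`, `truth` (per-sample state and diet, per-genus CAG,
#'   subject map), and the `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_subjects = 6, n_otus = 40,
#'                                            n_genera = 10, seed = 7))
#' cohort
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  tree <- generate_tree(config$n_otus, seed = config$seed)
  otus <- generate_otu_table(config)
  ffq <- generate_ffq(config, otus$truth$state)
  metadata <- generate_metadata(config, otus$table, otus$truth$state)
  truth <- otus$truth
  truth$diet <- ffq$truth_diet
  structure(list(otu_table = otus$table, tree = tree, ffq = ffq$ffq,
                 metadata = metadata, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d subjects x %d time points, %d OTUs ",
                     "(%d genera), %d states, %d diet groups, seed %d\n"),
              x$config$n_subjects, x$config$n_timepoints, x$config$n_otus,
              x$config$n_genera, x$config$n_states, x$config$n_diet_groups,
              x$config$seed))
  invisible(x)
}
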