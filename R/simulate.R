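#' Configuration for the synthetic evidence generator
#'
#' Defaults emulate the structure of the packaged case-study dataset: every
#' candidate is a documented constituent (`p_constituent = 1`), symptom
#' coverage is skewed toward well-studied compounds
#' (`symptom_count_distribution` close to the empirical 3/8/9/15 split over
#' levels 0..3), about 70% of candidates have a reported concentration,
#' concentrations span 10 to 10^6 ppm log-uniformly, and standards/methods
#' are available for about 80% of candidates.  Toxicants are absent from
#' the case study, so `p_toxic` defaults to 0.
#'
#' @param n_compounds Number of synthetic compound records.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param p_constituent Probability that component A is 1.
#' @param symptom_count_distribution Probabilities of symptom-coverage
#'   levels 0, 1, 2, 3+ (component B); must sum to 1.
#' @param p_concentration_determined Probability a concentration exists.
#' @param ppm_log_range Log10 range (low, high) the true ppm is drawn from,
#'   uniformly on the log scale.
#' @param p_standard,p_method Probability of an available reference
#'   standard / assay method.
#' @param p_toxic Probability of the toxicant (must-screen) flag.
#' @param corrupt_k Number of records whose recorded scores are corrupted
#'   (for audit testing); 0 leaves recorded scores absent.
#' @return An `hm_sim_config` list.
#' @export
simulation_config <- function(n_compounds = 35L, seed = 1L,
                              p_constituent = 1,
                              symptom_count_distribution =
                                c(`0` = 0.1, `1` = 0.2, `2` = 0.3,
                                  `3` = 0.4),
                              p_concentration_determined = 0.7,
                              ppm_log_range = c(1, 6),
                              p_standard = 0.8, p_method = 0.8,
                              p_toxic = 0, corrupt_k = 0L) {
  probs <- c(p_constituent, p_concentration_determined, p_standard,
             p_method, p_toxic)
  stopifnot(
    n_compounds >= 1L,
    all(probs >= 0 & probs <= 1),
    length(symptom_count_distribution) == 4L,
    all(symptom_count_distribution >= 0),
    abs(sum(symptom_count_distribution) - 1) < 1e-8,
    length(ppm_log_range) == 2L, ppm_log_range[1] < ppm_log_range[2],
    corrupt_k >= 0L
  )
  if (corrupt_k > n_compounds) {
    stop("corrupt_k cannot exceed n_compounds", call. = FALSE)
  }
  structure(
    list(n_compounds = as.integer(n_compounds), seed = as.integer(seed),
         p_constituent = p_constituent,
         symptom_count_distribution = symptom_count_distribution,
         p_concentration_determined = p_concentration_determined,
         ppm_log_range = ppm_log_range, p_standard = p_standard,
         p_method = p_method, p_toxic = p_toxic,
         corrupt_k = as.integer(corrupt_k)),
    class = "hm_sim_config"
  )
}

#' Generate a synthetic evidence dataset with known ground truth
#'
#' Builds a dataset of synthetic compound records whose evidence is
#' constructed so that [score_components()] must return a known set of
#' component scores: symptom lists are sized to the drawn coverage level,
#' the true concentration is drawn log-uniformly in ppm and then
#' re-expressed in a random unit (percent w/w, mg/g, ppm) as a point value
#' or a symmetric range whose midpoint reproduces the drawn ppm, and
#' standards/methods lists are populated according to the drawn
#' availability flags.  With `corrupt_k > 0`, the true scores are first
#' planted as recorded scores on every record and then `corrupt_k` records
#' are corrupted, one field each, per the returned ledger; each corruption
#' produces exactly one audit finding (see [audit_dataset()]).
#'
#' @param config An `hm_sim_config` from [simulation_config()].
#' @return List with `dataset` (an `hm_dataset`) and `truth`: a list with
#'   `components` (tibble of true a..f and total per compound) and
#'   `ledger` (tibble of planted corruptions: `compound_id`, `field`,
#'   `original`, `corrupted`, `kind`).
#' @export
#' @examples
#' sim <- generate_dataset(simulation_config(n_compounds = 5, seed = 42))
#' sim$truth$components
generate_dataset <- function(config) {
  stopifnot(inherits(config, "hm_sim_config"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)

  pool <- sprintf("synthetic symptom %02d", 1:8)
  plant <- hm_plant(
    botanical_name = "Synthetica exemplaris", family = "Syntheticaceae",
    source = "cultivated", part_used = "leaf", dosage_forms = "syrup",
    indications = list(hm_indication("synthetic condition", pool))
  )

  units <- c("percent_w_w", "mg_per_g", "ppm")
  factors <- c(percent_w_w = 1e4, mg_per_g = 1e3, ppm = 1)

  records <- vector("list", config$n_compounds)
  truth_rows <- vector("list", config$n_compounds)
  for (i in seq_len(config$n_compounds)) {
    id <- sprintf("SYN%05d", i)
    a <- as.integer(runif(1) < config$p_constituent)
    b <- sample(0:3, 1L, prob = config$symptom_count_distribution)
    activities <- if (b > 0L) {
      list(hm_activity("synthetic activity",
                       symptoms_addressed = sample(pool, b),
                       relevant_to_indication = TRUE,
                       mechanism = "synthetic mechanism",
                       citations = "SYN"))
    } else list()

    determined <- runif(1) < config$p_concentration_determined
    if (determined) {
      ppm_true <- 10^runif(1, config$ppm_log_range[1],
                           config$ppm_log_range[2])
      unit <- sample(units, 1L)
      fac <- factors[[unit]]
      if (runif(1) < 0.5) {
        lo <- ppm_true; hi <- ppm_true
      } else {
        delta <- ppm_true * runif(1, 0.05, 0.5)
        lo <- ppm_true - delta; hi <- ppm_true + delta
      }
      conc <- hm_concentration(raw_text = "", determined = TRUE,
                               low = lo / fac, high = hi / fac, unit = unit,
                               basis = "synthetic matrix")
      conc$raw_text <- format_concentration(conc)
      # truth from the report exactly as stored (guards the 5/50 thresholds
      # against representation round-off)
      mid <- (conc$low * fac + conc$high * fac) / 2
      c_pt <- as.integer(mid >= 5)
      d_pt <- as.integer(mid >= 50)
    } else {
      conc <- hm_concentration("ND", determined = FALSE)
      c_pt <- 0L; d_pt <- 0L
    }

    e <- as.integer(runif(1) < config$p_standard)
    f <- as.integer(runif(1) < config$p_method)
    standards <- if (e == 1L) {
      list(hm_standard_listing("SynChem", "analytical standard",
                               pack_value = 10,
                               pack_unit = "mg",
                               price_eur = round(runif(1, 10, 600), 2)))
    } else list()
    methods <- if (f == 1L) {
      list(hm_method_listing("HPLC-UV", "synthetic matrix", "SYN"))
    } else list()

    records[[i]] <- hm_compound_record(
      compound_id = id, name = sprintf("syntheticin %05d", i),
      plant = plant$botanical_name,
      documented_constituent = a == 1L, activities = activities,
      concentration = conc, standards = standards, methods = methods,
      toxic = runif(1) < config$p_toxic
    )
    truth_rows[[i]] <- tibble(compound_id = id, a = a, b = b, c = c_pt,
                              d = d_pt, e = e, f = f,
                              total = a + b + c_pt + d_pt + e + f)
  }
  truth <- dplyr::bind_rows(truth_rows)

  ledger <- tibble(compound_id = character(), field = character(),
                   original = integer(), corrupted = integer(),
                   kind = character())
  if (config$corrupt_k > 0L) {
    for (i in seq_len(config$n_compounds)) {
      t <- truth[i, ]
      records[[i]]$recorded_components <-
        hm_component_scores(t$a, t$b, t$c, t$d, t$e, t$f)
      records[[i]]$recorded_total <- t$total
    }
    victims <- sample(config$n_compounds, config$corrupt_k)
    for (i in victims) {
      t <- truth[i, ]
      field <- sample(c("total", "b", "c", "e"), 1L)
      rec <- records[[i]]
      if (field == "total") {
        orig <- t$total
        new <- sample(setdiff(0:8, orig), 1L)
        rec$recorded_total <- as.integer(new)
        kind <- "sum_mismatch"
      } else {
        orig <- t[[field]]
        new <- if (field == "b") sample(setdiff(0:3, orig), 1L) else
          1L - orig
        rc <- rec$recorded_components
        rc[[field]] <- as.integer(new)
        rc$total <- rc$a + rc$b + rc$c + rc$d + rc$e + rc$f
        rec$recorded_components <- rc
        # keep the recorded total consistent so exactly one finding results
        rec$recorded_total <- rc$total
        kind <- if (field == "e") "availability_mismatch" else
          "derivation_mismatch"
      }
      records[[i]] <- rec
      ledger <- dplyr::bind_rows(ledger, tibble(
        compound_id = rec$compound_id, field = field,
        original = as.integer(orig), corrupted = as.integer(new),
        kind = kind))
    }
    ledger <- ledger[order(ledger$compound_id), ]
  }

  list(
    dataset = hm_dataset(plants = list(plant), compounds = records),
    truth = list(components = truth, ledger = ledger)
  )
}

#' Enumerate the admissible component space
#'
#' All combinations of the six rubric components that respect the
#' structural constraint `d <= c` (a concentration of at least 50 ppm is
#' also at least 5 ppm): `2 x 4 x 3 x 2 x 2 = 96` admissible vectors, each
#' with its brute-force total.  Serves as the exhaustive oracle for
#' [score_components()].
#'
#' @return Tibble with columns `a`, `b`, `c`, `d`, `e`, `f`, `total`
#'   (96 rows).
#' @export
enumerate_component_space <- function() {
  cd <- list(c(0L, 0L), c(1L, 0L), c(1L, 1L))
  grid <- expand.grid(a = 0:1, b = 0:3, cd = seq_along(cd), e = 0:1,
                      f = 0:1, KEEP.OUT.ATTRS = FALSE)
  out <- tibble(
    a = as.integer(grid$a), b = as.integer(grid$b),
    c = vapply(cd[grid$cd], `[[`, 0L, 1L),
    d = vapply(cd[grid$cd], `[[`, 0L, 2L),
    e = as.integer(grid$e), f = as.integer(grid$f)
  )
  out$total <- out$a + out$b + out$c + out$d + out$e + out$f
  out
}
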