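#' Simulate a toy phenotype ontology
#'
#' Builds a random is_a DAG shaped like a phenotype ontology: a global
#' root, a "phenotypic abnormality" branch fanning out into
#' organ-system subtrees of internal and leaf terms (with occasional
#' diamond edges, i.e. a second parent), and a small "routine encounter
#' concept" branch whose leaves model administrative/visit codes that
#' pad encounters without carrying case-control signal.
#'
#' @param n_terms Number of terms in the phenotype branch (systems +
#'   internal + leaves), excluding the two branch roots.
#' @param n_filler Number of routine-branch leaf terms.
#' @param n_systems Number of organ-system terms directly under the
#'   phenotype root.
#' @param p_diamond Probability that a term receives a second parent.
#' @param seed Optional seed (uses the current RNG state when `NULL`).
#' @return An `onto_graph` with a `roles` attribute: tibble `term`,
#'   `role` in root/pheno_root/system/internal/leaf/routine.
#' @export
simulate_ontology <- function(n_terms = 120, n_filler = 10, n_systems = 8,
                              p_diamond = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_terms >= n_systems + 1, n_systems >= 1)
  id <- function(i) sprintf("SIM:%07d", i)
  root <- id(1)
  pheno_root <- id(2)
  routine_root <- id(3)
  n_sys <- n_systems
  sys_ids <- id(3 + seq_len(n_sys))
  rest <- n_terms - n_sys
  rest_ids <- if (rest > 0) id(3 + n_sys + seq_len(rest)) else character(0)
  filler_ids <- if (n_filler > 0) {
    id(3 + n_sys + rest + seq_len(n_filler))
  } else character(0)
  child <- c(pheno_root, routine_root, sys_ids, filler_ids)
  parent <- c(root, root, rep(pheno_root, n_sys),
              rep(routine_root, length(filler_ids)))
  # each remaining phenotype term attaches below an earlier term of its
  # system branch; construction order guarantees acyclicity
  pool <- sys_ids
  for (t in rest_ids) {
    p1 <- sample(pool, 1)
    child <- c(child, t)
    parent <- c(parent, p1)
    if (stats::runif(1) < p_diamond && length(pool) > 1) {
      p2 <- sample(setdiff(pool, p1), 1)
      child <- c(child, t)
      parent <- c(parent, p2)
    }
    pool <- c(pool, t)
  }
  terms <- c(root, pheno_root, routine_root, sys_ids, rest_ids, filler_ids)
  edges <- tibble::tibble(child = child, parent = parent)
  labels <- stats::setNames(paste0("simulated term ", seq_along(terms)),
                            terms)
  labels[root] <- "all"
  labels[pheno_root] <- "phenotypic abnormality (simulated)"
  labels[routine_root] <- "routine encounter concept (simulated)"
  g <- new_onto_graph(terms, edges, labels)
  assert_acyclic(g)
  has_child <- lengths(g$children) > 0
  role <- dplyr::case_when(
    terms == root ~ "root",
    terms == pheno_root ~ "pheno_root",
    terms == routine_root ~ "routine_root",
    terms %in% sys_ids ~ "system",
    terms %in% filler_ids ~ "routine",
    has_child[terms] ~ "internal",
    TRUE ~ "leaf"
  )
  attr(g, "roles") <- tibble::tibble(term = terms, role = role)
  g
}

#' Simulation configuration
#'
#' Assembles the full parameter set for [simulate_cohort()]. Defaults
#' emulate a discovery-scale childhood-onset epilepsy case-control
#' cohort: 259 cases and 244 matched-style controls observed from
#' infancy with a mean follow-up of about 8 years, a piecewise-constant
#' encounter-rate curve with a case-specific 1.7x bump at ages 18-20
#' (the care-transition years), negative-binomial concepts per encounter
#' with a higher case mean, per-leaf-term carrier prevalence with
#' odds-scaled planted effects in cases, log-normal costs by setting,
#' and a prescription model calibrated to means of about 4.5 vs 3.2
#' unique ASMs and 12 vs 8 rescue prescriptions per person.
#'
#' @param n_cases,n_controls Group sizes.
#' @param seed Integer seed; all randomness (including per-person
#'   substreams) derives from it.
#' @param ontology An `onto_graph` from [simulate_ontology()], or `NULL`
#'   to simulate one with `n_terms`/`n_filler`.
#' @param n_terms,n_filler Ontology size when `ontology` is `NULL`.
#' @param baseline_prevalence Per-leaf-term carrier probability in
#'   controls (scalar or named per-term vector).
#' @param planted_effects Tibble `term`, `or`, optional `bin` (an
#'   [age_bins()] label restricting the effect, NA = unrestricted).
#'   Planted terms must be phenotype leaves.
#' @param encounter_rates Tibble `group`, `lo`, `hi`, `rate`:
#'   piecewise-constant annual encounter rates per group.
#' @param transition_bump Multiplier on the case rate inside
#'   `bump_ages` (default 1.7).
#' @param bump_ages Length-2 ages (default `c(18, 20)`).
#' @param followup List: `first_max` (first encounter age is uniform on
#'   `[0, first_max]`), `mean`, `sd` (gamma follow-up span), `max_age`,
#'   `full` (`TRUE` observes everyone over `[0, max_age]`, used for
#'   parameter-recovery experiments).
#' @param concept_mu,concept_size Negative-binomial concepts-per-
#'   encounter parameters; `concept_mu` is named `c(case=, control=)`.
#' @param carrier_share Probability that a concept slot draws from the
#'   person's carrier term set rather than the routine pool.
#' @param setting_probs Named probabilities for
#'   outpatient/emergency/inpatient settings.
#' @param cost_params Tibble `setting`, `meanlog`, `sdlog` for
#'   log-normal costs; `cost_case_mult` scales case costs.
#' @param cost_case_mult Multiplicative case shift on costs.
#' @param catalogue Drug catalogue ([asm_dictionary()] format) or `NULL`
#'   to skip prescriptions.
#' @param exposure_p Named per-drug exposure probability
#'   `c(case=, control=)`.
#' @param rescue_mean_events Named mean rescue-prescription events per
#'   exposed person `c(case=, control=)`.
#' @param diagnosis_age_mean Named mean age (years) at the first
#'   epilepsy billing code `c(case=, control=)`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_cases = 259,
                       n_controls = 244,
                       seed = 1,
                       ontology = NULL,
                       n_terms = 120,
                       n_filler = 10,
                       baseline_prevalence = 0.05,
                       planted_effects = NULL,
                       encounter_rates = NULL,
                       transition_bump = 1.7,
                       bump_ages = c(18, 20),
                       followup = list(first_max = 0.4, mean = 8.2, sd = 5,
                                       max_age = 22, full = FALSE),
                       concept_mu = c(case = 6.5, control = 4.7),
                       concept_size = 3,
                       carrier_share = 0.5,
                       setting_probs = c(outpatient = 0.85,
                                         emergency = 0.10,
                                         inpatient = 0.05),
                       cost_params = NULL,
                       cost_case_mult = 390 / 370,
                       catalogue = asm_dictionary(),
                       exposure_p = c(case = 0.203, control = 0.145),
                       rescue_mean_events = c(case = 11.7, control = 11.2),
                       diagnosis_age_mean = c(case = 1.87, control = 2.09)) {
  stopifnot(n_cases >= 1, n_controls >= 1,
            all(baseline_prevalence > 0 & baseline_prevalence < 1),
            transition_bump > 0)
  if (is.null(encounter_rates)) {
    encounter_rates <- tidyr::expand_grid(
      group = c("case", "control"),
      tibble::tibble(lo = c(0, 2, 12, 18), hi = c(2, 12, 18, Inf),
                     rate = c(4, 2, 1.8, 2.1))
    )
    encounter_rates$rate[encounter_rates$group == "case"] <-
      encounter_rates$rate[encounter_rates$group == "case"] * 1.15
  }
  if (is.null(cost_params)) {
    cost_params <- tibble::tibble(
      setting = c("outpatient", "emergency", "inpatient"),
      meanlog = log(c(370, 1200, 5000)),
      sdlog = c(0.29, 0.8, 1.0)
    )
  }
  if (is.null(planted_effects)) {
    planted_effects <- tibble::tibble(term = character(0), or = numeric(0),
                                      bin = character(0))
  }
  planted_effects <- tibble::as_tibble(planted_effects)
  if (!"bin" %in% names(planted_effects)) planted_effects$bin <- NA_character_
  stopifnot(all(planted_effects$or > 0), all(is.finite(planted_effects$or)))
  fu_default <- list(first_max = 0.4, mean = 8.2, sd = 5, max_age = 22,
                     full = FALSE)
  followup <- utils::modifyList(fu_default, followup)
  structure(
    list(n_cases = n_cases, n_controls = n_controls, seed = seed,
         ontology = ontology, n_terms = n_terms, n_filler = n_filler,
         baseline_prevalence = baseline_prevalence,
         planted_effects = planted_effects,
         encounter_rates = encounter_rates,
         transition_bump = transition_bump, bump_ages = bump_ages,
         followup = followup, concept_mu = concept_mu,
         concept_size = concept_size, carrier_share = carrier_share,
         setting_probs = setting_probs, cost_params = cost_params,
         cost_case_mult = cost_case_mult, catalogue = catalogue,
         exposure_p = exposure_p, rescue_mean_events = rescue_mean_events,
         diagnosis_age_mean = diagnosis_age_mean),
    class = "sim_config"
  )
}

#' A symmetric null configuration
#'
#' A [sim_config()] in which every group-dependent parameter is
#' equalized and no effects are planted, so that any downstream
#' case-control association is a false positive. Used for family-wise
#' error calibration.
#'
#' @param n_per_arm Persons per group.
#' @param n_terms Phenotype-branch ontology size.
#' @param seed Seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
null_config <- function(n_per_arm = 200, n_terms = 500, seed = 1, ...) {
  rates <- tidyr::expand_grid(
    group = c("case", "control"),
    tibble::tibble(lo = c(0, 18), hi = c(18, Inf), rate = c(2, 2))
  )
  sim_config(
    n_cases = n_per_arm, n_controls = n_per_arm, seed = seed,
    n_terms = n_terms,
    encounter_rates = rates, transition_bump = 1,
    concept_mu = c(case = 5, control = 5),
    cost_case_mult = 1,
    exposure_p = c(case = 0.15, control = 0.15),
    rescue_mean_events = c(case = 10, control = 10),
    diagnosis_age_mean = c(case = 2, control = 2),
    ...
  )
}

# piecewise-constant rate lookup; seg is a plain list(lo, hi, rate)
rate_vector <- function(seg, ages) {
  r <- numeric(length(ages))
  for (i in seq_along(seg$lo)) {
    in_seg <- ages >= seg$lo[i] & ages < seg$hi[i]
    r[in_seg] <- seg$rate[i]
  }
  r
}

# per-group rate segments with the case transition bump folded in
rate_segments <- function(cfg) {
  lapply(c(case = "case", control = "control"), function(gr) {
    seg <- cfg$encounter_rates[cfg$encounter_rates$group == gr, ]
    seg <- list(lo = seg$lo, hi = seg$hi, rate = seg$rate)
    if (gr == "case" && cfg$transition_bump != 1) {
      # split segments at the bump boundaries, then scale inside
      cuts <- sort(unique(c(seg$lo, seg$hi, cfg$bump_ages)))
      cuts <- cuts[cuts >= min(seg$lo)]
      lo <- utils::head(cuts, -1)
      hi <- utils::tail(cuts, -1)
      rate <- rate_vector(seg, lo)
      in_bump <- lo >= cfg$bump_ages[1] & hi <= cfg$bump_ages[2]
      rate[in_bump] <- rate[in_bump] * cfg$transition_bump
      seg <- list(lo = lo, hi = hi, rate = rate)
    }
    seg
  })
}

#' Simulate a case-control EHR cohort
#'
#' Generates persons, encounters, coded events (eligibility codes plus
#' concept annotations), and prescriptions under a [sim_config()]. The
#' generative model, per person: demographics from category frequencies;
#' an observation window (first encounter age, gamma follow-up span);
#' encounter ages from a piecewise-constant Poisson process with the
#' group's rate curve (cases get the transition bump); per-leaf-term
#' carrier status from the baseline prevalence, odds-scaled in cases for
#' planted effects (so a planted odds ratio is the person-level carrier
#' odds ratio the association scan estimates); per-encounter concept
#' counts from a negative binomial, slots split between the person's
#' carrier terms and the routine pool, with every carrier term forced to
#' appear at least once (inside its age bin for bin-restricted effects);
#' log-normal costs per setting; and catalogue-based prescriptions.
#'
#' The global seed fans out into one RNG substream per person, so
#' regenerating any subset of persons reproduces their records exactly.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_cohort`: `persons`, `encounters`, `events`,
#'   `prescriptions`, `ontology`, `concept_map`, `carriers` (the true
#'   person-by-leaf carrier tibble, for recovery diagnostics), `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  g <- cfg$ontology %||% simulate_ontology(cfg$n_terms, cfg$n_filler)
  roles <- attr(g, "roles")
  if (is.null(roles)) {
    # user-supplied ontology: leaves are phenotype pool, no routine pool
    has_child <- lengths(g$children) > 0
    roles <- tibble::tibble(
      term = g$terms,
      role = ifelse(has_child[g$terms], "internal", "leaf")
    )
  }
  leaves <- roles$term[roles$role == "leaf"]
  routine <- roles$term[roles$role == "routine"]
  if (length(routine) == 0) routine <- leaves  # degenerate fallback
  missing_planted <- setdiff(cfg$planted_effects$term, leaves)
  if (length(missing_planted) > 0) {
    stop("planted terms are not phenotype leaves of the ontology: ",
         paste(missing_planted, collapse = ", "), call. = FALSE)
  }
  L <- length(leaves)
  p_ctrl <- rep_len(cfg$baseline_prevalence, L)
  names(p_ctrl) <- leaves
  if (!is.null(names(cfg$baseline_prevalence)) &&
      all(leaves %in% names(cfg$baseline_prevalence))) {
    p_ctrl <- cfg$baseline_prevalence[leaves]
  }
  p_case <- p_ctrl
  or_k <- rep(1, L)
  names(or_k) <- leaves
  or_k[cfg$planted_effects$term] <- cfg$planted_effects$or
  odds <- p_ctrl / (1 - p_ctrl) * or_k
  p_case <- odds / (1 + odds)
  term_bin <- stats::setNames(rep(NA_character_, L), leaves)
  term_bin[cfg$planted_effects$term] <- cfg$planted_effects$bin
  bins <- age_bins()
  bin_lo <- stats::setNames(bins$lo, as.character(bins$bin))
  bin_hi <- stats::setNames(bins$hi, as.character(bins$bin))
  routine_w <- 1 / seq_along(routine)  # Zipf-ish commonness

  n <- cfg$n_cases + cfg$n_controls
  ids <- sprintf("P%05d", seq_len(n))
  group <- rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))
  sex <- sample(c("female", "male"), n, replace = TRUE,
                prob = c(0.46, 0.54))
  ancestry <- sample(
    c("hispanic_or_latino", "not_hispanic_or_latino", "unknown"),
    n, replace = TRUE, prob = c(0.08, 0.885, 0.035))
  person_seed <- sample.int(.Machine$integer.max - 1L, n)

  enc_acc <- vector("list", n)
  ev_acc <- vector("list", n)
  rx_acc <- vector("list", n)
  car_acc <- vector("list", n)
  fu <- cfg$followup
  mu_named <- cfg$concept_mu
  cat_rx <- cfg$catalogue
  segs <- rate_segments(cfg)
  cost_meanlog <- stats::setNames(cfg$cost_params$meanlog,
                                  cfg$cost_params$setting)
  cost_sdlog <- stats::setNames(cfg$cost_params$sdlog,
                                cfg$cost_params$setting)

  for (i in seq_len(n)) {
    set.seed(person_seed[i])
    gi <- group[i]
    # observation window
    if (isTRUE(fu$full)) {
      first <- 0
      last <- fu$max_age
    } else {
      first <- stats::runif(1, 0, fu$first_max)
      shape <- (fu$mean / fu$sd)^2
      span <- stats::rgamma(1, shape = shape, rate = shape / fu$mean)
      last <- min(first + max(span, 0.1), fu$max_age)
    }
    # encounters: Poisson counts per age-year segment
    years <- seq(floor(first), ceiling(last) - 1)
    lo <- pmax(years, first)
    hi <- pmin(years + 1, last)
    len <- pmax(hi - lo, 0)
    lambda <- rate_vector(segs[[gi]], years + 1e-9) * len
    counts <- stats::rpois(length(years), lambda)
    ages <- unlist(mapply(function(k, a, b) stats::runif(k, a, b),
                          counts, lo, hi, SIMPLIFY = FALSE),
                   use.names = FALSE)
    if (length(ages) == 0) ages <- stats::runif(1, first, max(last, first + 0.1))
    ages <- sort(round(ages, 6))  # ~30 s resolution; exact in text formats
    E <- length(ages)
    setting <- sample(names(cfg$setting_probs), E, replace = TRUE,
                      prob = cfg$setting_probs)
    shift <- if (gi == "case") log(cfg$cost_case_mult) else 0
    cost <- stats::rlnorm(E, cost_meanlog[setting] + shift,
                          cost_sdlog[setting])
    enc_acc[[i]] <- list(person_id = rep(ids[i], E), age_years = ages,
                         setting = setting, cost = round(cost, 2))
    # carrier terms
    pv <- if (gi == "case") p_case else p_ctrl
    carrier <- leaves[stats::runif(L) < pv]
    car_acc[[i]] <- list(person_id = rep(ids[i], length(carrier)),
                         term = carrier)
    # concept draws per encounter
    mu <- unname(mu_named[gi])
    n_slots <- stats::rnbinom(E, mu = mu, size = cfg$concept_size)
    total <- sum(n_slots)
    ev_term <- character(0)
    ev_age <- numeric(0)
    if (total > 0) {
      slot_enc <- rep.int(seq_len(E), n_slots)
      from_carrier <- stats::runif(total) < cfg$carrier_share &
        length(carrier) > 0
      pick <- character(total)
      if (any(from_carrier)) {
        pick[from_carrier] <- sample(carrier, sum(from_carrier),
                                     replace = TRUE)
      }
      if (any(!from_carrier)) {
        pick[!from_carrier] <- sample(routine, sum(!from_carrier),
                                      replace = TRUE, prob = routine_w)
      }
      # bin-restricted carrier terms may only be observed inside their bin
      tb <- term_bin[pick]
      ok <- is.na(tb) | !(pick %in% carrier)
      in_bin <- !is.na(tb) &
        ages[slot_enc] >= bin_lo[tb] & ages[slot_enc] < bin_hi[tb]
    ok <- ok | in_bin
      ev_term <- pick[ok]
      ev_age <- ages[slot_enc][ok]
    }
    # force each carrier term to appear at least once (inside its bin)
    for (t in carrier) {
      b <- term_bin[[t]]
      elig <- if (is.na(b)) ages else
        ages[ages >= bin_lo[[b]] & ages < bin_hi[[b]]]
      if (length(elig) == 0) next  # not expressible in this person
      if (!t %in% ev_term || (!is.na(b) &&
                              !any(ev_term == t & ev_age >= bin_lo[[b]] &
                                     ev_age < bin_hi[[b]]))) {
        ev_term <- c(ev_term, t)
        ev_age <- c(ev_age, elig[sample.int(length(elig), 1)])
      }
    }
    # eligibility codes: epilepsy diagnosis + EEG
    dx_mean <- unname(cfg$diagnosis_age_mean[gi])
    dx_age <- round(
      min(max(stats::rgamma(1, shape = 4, rate = 4 / dx_mean), 0.05), 4.9),
      6)
    n_ev <- length(ev_term)
    ev_acc[[i]] <- list(
      person_id = rep(ids[i], n_ev + 2L),
      age_years = c(ev_age, dx_age, dx_age),
      code_system = c(rep("UMLS", n_ev), "ICD10", "CPT"),
      code = c(if (n_ev > 0) paste0("U", sub("SIM:", "", ev_term)) else
        character(0), "G40.9", "EEG1")
    )
    # prescriptions
    if (!is.null(cat_rx) && nrow(cat_rx) > 0) {
      pexp <- unname(cfg$exposure_p[gi])
      exposed <- stats::runif(nrow(cat_rx)) < pexp
      if (any(exposed)) {
        drugs <- cat_rx[exposed, ]
        n_events <- ifelse(
          drugs$is_rescue,
          1L + stats::rnbinom(nrow(drugs),
                              mu = unname(cfg$rescue_mean_events[gi]) - 1,
                              size = 2),
          1L + stats::rpois(nrow(drugs), 2))
        rx_drug <- rep(drugs$drug, n_events)
        rx_class <- rep(drugs$drug_class, n_events)
        rx_asm <- rep(drugs$is_asm, n_events)
        rx_age <- round(stats::runif(length(rx_drug), first, last), 6)
        rx_acc[[i]] <- list(person_id = rep(ids[i], length(rx_drug)),
                            age_years = rx_age, drug = rx_drug,
                            drug_class = rx_class, is_asm = rx_asm)
      }
    }
  }

  persons <- tibble::tibble(id = ids, person_id = ids, sex = sex,
                            ancestry = ancestry, group = group,
                            tested = group == "case")
  persons$id <- NULL
  bind_chunks <- function(acc) {
    acc <- acc[!vapply(acc, is.null, TRUE)]
    if (length(acc) == 0) return(tibble::tibble())
    cols <- names(acc[[1]])
    tibble::as_tibble(stats::setNames(
      lapply(cols, function(cn) {
        unlist(lapply(acc, `[[`, cn), use.names = FALSE)
      }), cols))
  }
  encounters <- bind_chunks(enc_acc)
  events <- bind_chunks(ev_acc)
  prescriptions <- bind_chunks(rx_acc)
  carriers <- bind_chunks(car_acc)
  mapped <- unique(events$code[events$code_system == "UMLS"])
  concept_map <- tibble::tibble(
    source_code = mapped,
    term_id = paste0("SIM:", sub("^U", "", mapped))
  )
  structure(
    list(persons = persons, encounters = encounters, events = events,
         prescriptions = prescriptions, ontology = g,
         concept_map = concept_map, carriers = carriers, config = cfg),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", nrow(x$persons), " persons (",
      sum(x$persons$group == "case"), " cases), ",
      nrow(x$encounters), " encounters, ", nrow(x$events),
      " coded events, ", nrow(x$prescriptions), " prescriptions\n",
      sep = "")
  invisible(x)
}

#' Annotations table of a simulated cohort
#'
#' Maps the simulated UMLS-style coded events through the bundled
#' concept map, returning pre-propagation annotations.
#'
#' @param sim A [simulate_cohort()] result.
#' @return Tibble `person_id`, `term`, `age_years`.
#' @export
sim_annotations <- function(sim) {
  umls <- dplyr::filter(sim$events, .data$code_system == "UMLS")
  map_concepts(umls, sim$concept_map, sim$ontology)
}

#' Write simulated data as plain-text fixtures
#'
#' Emits the exact file dialects the readers consume: `persons.csv`,
#' `events.csv`, `encounters.csv`, `prescriptions.csv`, `toy.obo`,
#' `concept_map.tsv`. Round-trips losslessly through
#' [read_cohort_files()] / [parse_obo()].
#'
#' @param sim A [simulate_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixtures <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    persons = file.path(out_dir, "persons.csv"),
    events = file.path(out_dir, "events.csv"),
    encounters = file.path(out_dir, "encounters.csv"),
    prescriptions = file.path(out_dir, "prescriptions.csv"),
    obo = file.path(out_dir, "toy.obo"),
    concept_map = file.path(out_dir, "concept_map.tsv")
  )
  readr::write_csv(sim$persons, paths["persons"])
  readr::write_csv(sim$events, paths["events"])
  readr::write_csv(sim$encounters, paths["encounters"])
  readr::write_csv(sim$prescriptions, paths["prescriptions"])
  write_obo(sim$ontology, paths["obo"])
  readr::write_tsv(sim$concept_map, paths["concept_map"])
  invisible(paths)
}

#' Read cohort input files
#'
#' Reads the persons/events/encounters/prescriptions tables written by
#' [write_fixtures()] (or prepared externally in the same dialect).
#'
#' @param dir Directory containing the files.
#' @return List of tibbles `persons`, `events`, `encounters`,
#'   `prescriptions` (the latter `NULL` when absent).
#' @export
read_cohort_files <- function(dir) {
  rd <- function(f, types) {
    readr::read_csv(file.path(dir, f), col_types = types, progress = FALSE)
  }
  persons <- rd("persons.csv", "ccccl")
  events <- rd("events.csv", "cdcc")
  encounters <- rd("encounters.csv", "cdcd")
  rx_path <- file.path(dir, "prescriptions.csv")
  prescriptions <- if (file.exists(rx_path)) {
    readr::read_csv(rx_path, col_types = "cdccl", progress = FALSE)
  } else NULL
  list(persons = persons, events = events, encounters = encounters,
       prescriptions = prescriptions)
}
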