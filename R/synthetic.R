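#' Define an antibody panel
#'
#' A panel is a named set of markers measured together in one staining tube;
#' the backbone is the subset shared by every panel of a multi-tube design
#' and is the coordinate system for cross-panel cell matching.
#'
#' @param panel_id panel name (e.g. `"#A"`).
#' @param markers character vector of marker names.
#' @param backbone character vector, a subset of `markers`.
#' @return an object of class `panel_definition`.
#' @export
panel_definition <- function(panel_id, markers, backbone) {
  if (anyDuplicated(markers)) {
    stop("duplicate marker in panel ", panel_id, call. = FALSE)
  }
  if (!all(backbone %in% markers)) {
    stop("backbone must be a subset of the panel markers", call. = FALSE)
  }
  structure(list(panel_id = panel_id, markers = markers, backbone = backbone),
            class = "panel_definition")
}

#' Define a synthetic cell population
#'
#' One leukocyte population is modelled as a diagonal multivariate normal in
#' arcsinh space: each marker is drawn independently from
#' `Normal(mean, sd)`. Condition-dependent biology is expressed two ways:
#' per-condition abundance weights, and an optional per-condition `shift`
#' added to the mean of selected markers (e.g. activation markers raised in
#' the disease condition).
#'
#' @param name population name.
#' @param mean named numeric vector, one mean (arcsinh units) per marker of
#'   the cohort's marker universe.
#' @param sd named numeric vector of per-marker standard deviations
#'   (non-negative; zero gives the degenerate point distribution), or a
#'   single value recycled over markers.
#' @param abundance named numeric vector of relative weights, one per
#'   condition (non-negative, not all zero).
#' @param shift optional named list: condition -> named numeric vector of
#'   mean offsets for a subset of markers.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(name, mean, sd, abundance, shift = NULL) {
  if (is.null(names(mean))) stop("mean must be a named vector", call. = FALSE)
  if (length(sd) == 1L) sd <- stats::setNames(rep(sd, length(mean)), names(mean))
  if (any(sd < 0)) stop("sd must be non-negative", call. = FALSE)
  if (any(abundance < 0) || all(abundance == 0)) {
    stop("abundance weights must be non-negative and not all zero",
         call. = FALSE)
  }
  structure(list(name = name, mean = mean, sd = sd, abundance = abundance,
                 shift = shift),
            class = "population_spec")
}

#' Define a synthetic multi-panel cohort
#'
#' Describes everything needed to simulate a two-condition, multi-tube
#' cytometry study: the populations, the full marker universe, the panels
#' (whose union must equal the universe and whose backbones must be
#' identical), the individuals with their conditions, the per-individual
#' event count, and the panel-specific measurement noise applied to
#' backbone markers when the single simulated profile is split into tubes.
#'
#' @param populations list of [population_spec()] objects.
#' @param marker_universe character vector of all marker names.
#' @param panels list of [panel_definition()] objects.
#' @param individuals named character vector: individual id -> condition.
#' @param n_events events simulated per individual.
#' @param backbone_noise_sd standard deviation of the i.i.d. Gaussian noise
#'   added independently per panel to each backbone column (arcsinh units);
#'   models tube-to-tube staining/measurement variation.
#' @param seed base seed for the cohort.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(populations, marker_universe, panels, individuals,
                        n_events = 5000, backbone_noise_sd = 0.05, seed = 1) {
  if (anyDuplicated(marker_universe)) {
    stop("duplicate marker in universe", call. = FALSE)
  }
  panel_union <- unique(unlist(lapply(panels, `[[`, "markers")))
  if (!setequal(panel_union, marker_universe)) {
    stop("union of panel markers must equal the marker universe",
         call. = FALSE)
  }
  bb <- lapply(panels, `[[`, "backbone")
  for (b in bb[-1]) {
    if (!setequal(b, bb[[1]])) {
      stop("all panels must share an identical backbone", call. = FALSE)
    }
  }
  for (pop in populations) {
    if (!all(marker_universe %in% names(pop$mean))) {
      stop("population '", pop$name,
           "' lacks a mean for some universe markers", call. = FALSE)
    }
  }
  conditions <- unique(unname(individuals))
  for (cond in conditions) {
    w <- vapply(populations, function(p) {
      v <- p$abundance[[cond]]
      if (is.null(v) || is.na(v)) 0 else v
    }, numeric(1))
    if (sum(w) <= 0) {
      stop("condition '", cond, "' has all-zero population weights",
           call. = FALSE)
    }
  }
  if (backbone_noise_sd < 0) stop("backbone_noise_sd must be >= 0",
                                  call. = FALSE)
  structure(
    list(populations = populations, marker_universe = marker_universe,
         panels = panels, individuals = individuals, n_events = n_events,
         backbone_noise_sd = backbone_noise_sd, seed = seed),
    class = "cohort_spec"
  )
}

#' Simulate one individual's full-universe profile
#'
#' Draws `n_events` cells in two steps: population labels are sampled with
#' the individual condition's normalized abundance weights, then each marker
#' is drawn independently from the population's normal (with any
#' condition-specific mean shift applied). The profile is returned directly
#' in arcsinh units with its `transformed` flag set; event ids `0..n-1`
#' carry the ground truth.
#'
#' @param spec a [cohort_spec()].
#' @param individual_id one of `names(spec$individuals)`.
#' @param seed RNG seed for this individual.
#' @return list with elements `profile` (a [cyto_profile()] over the full
#'   marker universe) and `truth` (data.frame of `event_id`, `population`).
#' @export
generate_individual <- function(spec, individual_id, seed = spec$seed) {
  cond <- spec$individuals[[individual_id]]
  if (is.null(cond)) stop("unknown individual: ", individual_id, call. = FALSE)
  mk <- spec$marker_universe
  w <- vapply(spec$populations, function(p) {
    v <- p$abundance[[cond]]
    if (is.null(v) || is.na(v)) 0 else v
  }, numeric(1))
  if (sum(w) <= 0) stop("condition '", cond, "' has all-zero weights",
                        call. = FALSE)
  pop_names <- vapply(spec$populations, `[[`, character(1), "name")
  n <- spec$n_events
  withr::with_seed(seed, {
    labels <- sample(pop_names, n, replace = TRUE, prob = w / sum(w))
    X <- matrix(stats::rnorm(n * length(mk)), n, length(mk),
                dimnames = list(NULL, mk))
    for (i in seq_along(spec$populations)) {
      pop <- spec$populations[[i]]
      rows <- which(labels == pop$name)
      if (!length(rows)) next
      mu <- pop$mean[mk]
      sh <- pop$shift[[cond]]
      if (!is.null(sh)) mu[names(sh)] <- mu[names(sh)] + sh
      X[rows, ] <- sweep(sweep(X[rows, , drop = FALSE], 2, pop$sd[mk], "*"),
                         2, mu, "+")
    }
  })
  prof <- cyto_profile(X, sample_id = individual_id, panel_id = "full",
                       event_ids = 0:(n - 1L), transformed = TRUE)
  list(profile = prof,
       truth = data.frame(event_id = 0:(n - 1L), population = labels,
                          stringsAsFactors = FALSE))
}

#' Split a full-universe profile into per-panel tubes
#'
#' Creates the multi-tube structure that backbone matching must invert: one
#' profile per panel restricted to that panel's markers, with independent
#' `Normal(0, backbone_noise_sd)` noise added to the backbone columns of
#' each tube and each tube's rows independently shuffled. Event ids follow
#' the shuffle so ground truth can score a later matching; the matcher
#' itself only ever sees the expression matrices.
#'
#' @param profile full-universe [cyto_profile()] (e.g. from
#'   [generate_individual()]).
#' @param panels list of [panel_definition()] objects.
#' @param backbone_noise_sd per-panel backbone noise SD (arcsinh units).
#' @param seed RNG seed.
#' @return named list of [cyto_profile()] objects, one per panel.
#' @export
split_panels <- function(profile, panels, backbone_noise_sd = 0, seed = 1) {
  out <- list()
  withr::with_seed(seed, {
    for (panel in panels) {
      missing <- setdiff(panel$markers, profile_markers(profile))
      if (length(missing)) {
        stop("panel ", panel$panel_id, " marker(s) absent from profile: ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      sub <- subset_markers(profile, panel$markers)
      if (backbone_noise_sd > 0 && nrow(sub$exprs) > 0) {
        nb <- length(panel$backbone)
        noise <- matrix(stats::rnorm(nrow(sub$exprs) * nb,
                                     sd = backbone_noise_sd),
                        nrow(sub$exprs), nb)
        sub$exprs[, panel$backbone] <- sub$exprs[, panel$backbone] + noise
      }
      ord <- sample.int(nrow(sub$exprs))
      sub$exprs <- sub$exprs[ord, , drop = FALSE]
      sub$event_ids <- profile$event_ids[ord]
      sub$panel_id <- panel$panel_id
      out[[panel$panel_id]] <- sub
    }
  })
  out
}

#' Preset synthetic cohort: treated-HIV versus healthy donors
#'
#' A ready-made two-condition cohort emulating a whole-blood leukocyte
#' study measured by three overlapping mass cytometry panels of 35, 32 and
#' 33 markers sharing a 14-marker backbone (72 markers in total). Eight
#' populations (CD4/CD8 T cells, B cells, NK cells, monocytes, PMNs, mDCs,
#' pDCs) are simulated for three healthy (`HEA`) and three treated-HIV
#' (`HIV`) individuals. In the HIV condition, activation and adhesion
#' markers (CD11a, CD11b, CD32, CD38, CD64, CD83, CD86, TLR2, among others)
#' are shifted upward by at least 1.0 arcsinh unit on monocytes and PMNs,
#' with related shifts on lymphocyte and dendritic populations, so disease
#' effects propagate to every downstream stage.
#'
#' @param seed cohort seed.
#' @param n_events events per individual (default 5000, the package's
#'   desk-scale run size).
#' @param backbone_noise_sd tube-to-tube backbone noise SD (default 0.05).
#' @return a [cohort_spec()].
#' @export
make_hiv_cohort_preset <- function(seed = 1, n_events = 5000,
                                   backbone_noise_sd = 0.05) {
  backbone <- c("CD1c", "CD3", "CD11c", "CD14", "CD16", "CD19", "CD32",
                "CD64", "CD66", "CD86", "CD123", "CD141", "Granzyme B",
                "HLADR")
  panel_a_specific <- c("CD8a", "IL-6", "Granzyme A", "IL-1b", "IL-8",
                        "CD23", "MIP-1b", "IP-10", "TNF-a", "IL-1a",
                        "IL-12", "CXCR4", "TLR2", "CCR5", "CD28", "IFN-a",
                        "CD45RA", "IFN-g", "CD4", "IL-1RA", "MCP-1")
  panel_b_specific <- c("CCR7", "NF-ATC", "CD335", "IL-4", "CD107a",
                        "CD154", "CD54", "IL-2", "CD69", "Ki67", "CD25",
                        "CD11a", "CD11b", "CD38", "IgG2b", "IL-10",
                        "MyD88", "Perforin")
  panel_c_specific <- c("CD209", "CD62L", "CD45", "CD137", "CXCR3", "CD56",
                        "ITGb7", "Bcl-6", "CD83", "CD279", "CD127",
                        "IL-10R", "CD27", "IgG2c", "CCL5", "IgG1K",
                        "IL-2RA", "IgG2a", "nfKB")
  universe <- c(backbone, panel_a_specific, panel_b_specific,
                panel_c_specific)
  panels <- list(
    panel_definition("#A", c(backbone, panel_a_specific), backbone),
    panel_definition("#B", c(backbone, panel_b_specific), backbone),
    panel_definition("#C", c(backbone, panel_c_specific), backbone)
  )

  base_mean <- function(...) {
    m <- stats::setNames(rep(0.2, length(universe)), universe)
    hi <- c(...)
    m[names(hi)] <- hi
    m
  }
  ab <- function(x) c(HEA = x, HIV = x)
  pops <- list(
    population_spec(
      "T CD4",
      base_mean("CD3" = 4, "CD4" = 3.5, "CD45" = 4, "CD28" = 3,
                "CD45RA" = 2.5, "CD127" = 3, "CD27" = 2.5, "CXCR4" = 1.5),
      sd = 0.3, abundance = ab(0.15),
      shift = list(HIV = c("CD11a" = 1, "CD27" = 1, "CD38" = 1.5,
                           "CD83" = 1, "CXCR4" = 1))),
    population_spec(
      "T CD8",
      base_mean("CD3" = 4, "CD8a" = 3.5, "CD45" = 4, "CD28" = 2.5,
                "CD27" = 2.5, "Granzyme A" = 1, "Granzyme B" = 1,
                "CXCR4" = 1.5),
      sd = 0.3, abundance = ab(0.10),
      shift = list(HIV = c("CD11a" = 1.5, "CD11b" = 1, "CD27" = 1,
                           "CD38" = 1.5, "CD83" = 1, "CXCR4" = 1.5,
                           "Granzyme A" = 2, "Granzyme B" = 2))),
    population_spec(
      "B cell",
      base_mean("CD19" = 4, "HLADR" = 3.5, "CD45" = 4, "CD32" = 2,
                "CXCR4" = 2),
      sd = 0.3, abundance = ab(0.08),
      shift = list(HIV = c("CD38" = 1.5, "CD83" = 1.5, "CXCR4" = 1,
                           "HLADR" = 1))),
    population_spec(
      "NK cell",
      base_mean("CD16" = 3.5, "CD56" = 3, "CD45" = 4, "Granzyme A" = 3,
                "Granzyme B" = 4, "Perforin" = 3.5, "CD11b" = 1),
      sd = 0.3, abundance = ab(0.07),
      shift = list(HIV = c("CD11a" = 1.5, "CD11b" = 1.5, "CD38" = 2,
                           "CXCR4" = 1.5, "Granzyme A" = 1.5,
                           "Granzyme B" = 1.5, "Perforin" = 1.5))),
    population_spec(
      "monocyte",
      base_mean("CD14" = 4.2, "CD11c" = 3.5, "HLADR" = 3.5, "CD64" = 3,
                "CD86" = 3, "CD32" = 2.5, "TLR2" = 2, "CD45" = 4,
                "CD11a" = 2, "CD11b" = 1),
      sd = 0.3, abundance = ab(0.12),
      shift = list(HIV = c("CD11a" = 1.5, "CD11b" = 2, "CD32" = 1.5,
                           "CD38" = 2, "CD64" = 1.2, "CD83" = 2,
                           "CD86" = 1.2, "TLR2" = 1.5, "MCP-1" = 1.5,
                           "CD11c" = 1))),
    population_spec(
      "PMN",
      base_mean("CD66" = 4, "CD16" = 2.5, "CD32" = 2, "CD45" = 2.5,
                "CD11a" = 1.5, "CD11b" = 1, "TLR2" = 1.5, "CD64" = 1),
      sd = 0.3, abundance = ab(0.45),
      shift = list(HIV = c("CD11a" = 1.5, "CD11b" = 2, "CD32" = 2,
                           "CD38" = 2, "CD64" = 2, "TLR2" = 1))),
    population_spec(
      "mDC",
      base_mean("CD11c" = 4, "HLADR" = 4.2, "CD1c" = 3.5, "CD86" = 2.5,
                "CD45" = 4, "CD11a" = 1.5, "TLR2" = 1.5, "CD83" = 1.5),
      sd = 0.3, abundance = ab(0.02),
      shift = list(HIV = c("CD11a" = 1, "CD11b" = 1, "CD83" = 1.5,
                           "CD86" = 1.5, "TLR2" = 1, "HLADR" = 1))),
    population_spec(
      "pDC",
      base_mean("CD123" = 4, "HLADR" = 3.8, "CD45" = 3.5, "CD141" = 1.5),
      sd = 0.3, abundance = ab(0.01),
      shift = list(HIV = c("CD11b" = 1.5, "Granzyme B" = 1,
                           "HLADR" = 0.5)))
  )
  individuals <- c("HEA-1" = "HEA", "HEA-2" = "HEA", "HEA-3" = "HEA",
                   "PAT-1" = "HIV", "PAT-2" = "HIV", "PAT-3" = "HIV")
  cohort_spec(pops, universe, panels, individuals, n_events = n_events,
              backbone_noise_sd = backbone_noise_sd, seed = seed)
}

#' Simulate a whole cohort of per-panel tubes
#'
#' Convenience wrapper: for each individual, draw the full-universe profile
#' and split it into panel tubes. Per-individual seeds are derived
#' deterministically from the cohort seed.
#'
#' @param spec a [cohort_spec()].
#' @return named list (by individual) of lists with elements `panels`
#'   (named list of per-panel profiles), `truth` (event_id -> population)
#'   and `full` (the unsplit profile).
#' @export
simulate_cohort <- function(spec) {
  out <- list()
  ids <- names(spec$individuals)
  for (i in seq_along(ids)) {
    id <- ids[i]
    ind_seed <- (spec$seed + 1009L * i) %% .Machine$integer.max
    gen <- generate_individual(spec, id, seed = ind_seed)
    tubes <- split_panels(gen$profile, spec$panels,
                          backbone_noise_sd = spec$backbone_noise_sd,
                          seed = ind_seed + 1L)
    out[[id]] <- list(panels = tubes, truth = gen$truth, full = gen$profile)
  }
  out
}
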