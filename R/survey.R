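#' Construct a survey dataset
#'
#' A `survey_dataset` pairs a binary site-by-species community matrix with a
#' site-by-variable environmental matrix over the same, identically ordered
#' sites. Repeat visits to a site are ordinary rows with their own record
#' identifiers.
#'
#' @param occurrence numeric matrix of 0/1 occurrences, sites in rows,
#'   species in columns. Dimnames are used as site and species identifiers
#'   when `site_ids` / `species_names` are not supplied.
#' @param environment numeric matrix of environmental variables, same rows.
#' @param site_ids,species_names,env_names optional identifier vectors.
#' @param normalized logical; `TRUE` when `environment` is already on
#'   \[0, 1\].
#' @param norm_params per-variable normalization parameters: a data frame
#'   with columns `variable`, `min`, `max`, recorded by
#'   [normalize_environment()].
#'
#' @return An object of class `survey_dataset`.
#' @seealso [read_survey()], [normalize_environment()],
#'   [filter_rare_species()]
#' @export
survey_dataset <- function(occurrence, environment,
                           site_ids = rownames(occurrence),
                           species_names = colnames(occurrence),
                           env_names = colnames(environment),
                           normalized = FALSE,
                           norm_params = NULL) {
  occurrence <- as.matrix(occurrence)
  environment <- as.matrix(environment)
  if (is.null(site_ids)) site_ids <- as.character(seq_len(nrow(occurrence)))
  if (is.null(species_names) && ncol(occurrence) > 0) {
    species_names <- paste0("sp", seq_len(ncol(occurrence)))
  }
  if (is.null(env_names) && ncol(environment) > 0) {
    env_names <- paste0("env", seq_len(ncol(environment)))
  }
  site_ids <- as.character(site_ids)
  species_names <- as.character(species_names %||% character(0))
  env_names <- as.character(env_names %||% character(0))
  dimnames(occurrence) <- list(site_ids, species_names)
  dimnames(environment) <- list(site_ids, env_names)
  obj <- structure(
    list(site_ids = site_ids,
         species_names = species_names,
         occurrence = occurrence,
         env_names = env_names,
         environment = environment,
         normalized = isTRUE(normalized),
         norm_params = norm_params),
    class = "survey_dataset")
  validate_survey(obj)
  obj
}

validate_survey <- function(data) {
  stopifnot(inherits(data, "survey_dataset"))
  if (nrow(data$occurrence) != nrow(data$environment)) {
    stop("occurrence and environment must cover the same sites (",
         nrow(data$occurrence), " vs ", nrow(data$environment), " rows)",
         call. = FALSE)
  }
  if (anyDuplicated(data$site_ids)) {
    stop("duplicated site identifiers: ",
         paste(unique(data$site_ids[duplicated(data$site_ids)]),
               collapse = ", "), call. = FALSE)
  }
  if (length(data$occurrence) > 0 && !is_binary_vector(c(data$occurrence))) {
    bad <- which(!(data$occurrence %in% c(0, 1)), arr.ind = TRUE)[1, ]
    stop("non-binary occurrence value at site '",
         data$site_ids[bad[1]], "', species '",
         data$species_names[bad[2]], "'", call. = FALSE)
  }
  if (length(data$environment) > 0 && !all(is.finite(data$environment))) {
    stop("environmental matrix contains non-finite values", call. = FALSE)
  }
  if (data$normalized && length(data$environment) > 0 &&
      (min(data$environment) < 0 || max(data$environment) > 1)) {
    stop("dataset is flagged normalized but environment values fall outside ",
         "[0, 1]", call. = FALSE)
  }
  invisible(data)
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("survey_dataset:", length(x$site_ids), "sites,",
      length(x$species_names), "species,",
      length(x$env_names), "environmental variables\n")
  cat("  normalized:", x$normalized, "\n")
  if (length(x$species_names) > 0) {
    prev <- colMeans(x$occurrence)
    cat("  prevalence range: [", sprintf("%.3f", min(prev)), ", ",
        sprintf("%.3f", max(prev)), "]\n", sep = "")
  }
  invisible(x)
}

#' Read paired community and environment tables
#'
#' Both CSV files must carry a site-identifier first column; rows are aligned
#' by identifier, with the community file defining the row order. Community
#' cells must be 0/1.
#'
#' @param community_path path to the site-by-species CSV.
#' @param environment_path path to the site-by-variable CSV.
#' @return A [survey_dataset()] with `normalized = FALSE`.
#' @export
read_survey <- function(community_path, environment_path) {
  comm <- utils::read.csv(community_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  env <- utils::read.csv(environment_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(comm) < 1 || ncol(env) < 1) {
    stop("both CSVs need a site-identifier first column", call. = FALSE)
  }
  comm_ids <- as.character(comm[[1]])
  env_ids <- as.character(env[[1]])
  only_comm <- setdiff(comm_ids, env_ids)
  only_env <- setdiff(env_ids, comm_ids)
  if (length(only_comm) || length(only_env)) {
    stop("site sets differ between tables; only in community: {",
         paste(only_comm, collapse = ", "), "}; only in environment: {",
         paste(only_env, collapse = ", "), "}", call. = FALSE)
  }
  occ <- as.matrix(comm[, -1, drop = FALSE])
  storage.mode(occ) <- "double"
  if (length(occ) > 0) {
    bad <- which(!(occ %in% c(0, 1)) | !is.finite(occ), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop("non-binary community value at row ", bad[1, 1], " (site '",
           comm_ids[bad[1, 1]], "'), column '",
           colnames(occ)[bad[1, 2]], "'", call. = FALSE)
    }
  }
  envm <- as.matrix(env[match(comm_ids, env_ids), -1, drop = FALSE])
  storage.mode(envm) <- "double"
  survey_dataset(occurrence = occ, environment = envm, site_ids = comm_ids)
}

#' Write a survey dataset to paired CSV files
#'
#' Environmental values are serialized with 17 significant digits so that a
#' read/write round trip reproduces them bit-exactly.
#'
#' @param data a [survey_dataset()].
#' @param community_path,environment_path output paths.
#' @return `data`, invisibly.
#' @export
write_survey <- function(data, community_path, environment_path) {
  validate_survey(data)
  comm <- data.frame(site = data$site_ids, check.names = FALSE)
  for (sp in data$species_names) comm[[sp]] <- as.integer(data$occurrence[, sp])
  env <- data.frame(site = data$site_ids, check.names = FALSE)
  for (v in data$env_names) {
    env[[v]] <- formatC(data$environment[, v], digits = 17, format = "g")
  }
  utils::write.csv(comm, community_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(env, environment_path, row.names = FALSE, quote = FALSE)
  invisible(data)
}

#' Subset a survey dataset by site
#'
#' @param data a [survey_dataset()].
#' @param idx logical or integer row index.
#' @return A [survey_dataset()] restricted to the selected sites.
#' @export
subset_sites <- function(data, idx) {
  survey_dataset(
    occurrence = data$occurrence[idx, , drop = FALSE],
    environment = data$environment[idx, , drop = FALSE],
    site_ids = data$site_ids[idx],
    species_names = data$species_names,
    env_names = data$env_names,
    normalized = data$normalized,
    norm_params = data$norm_params)
}

exclusion_report <- function(removed_rare = data.frame(species = character(0),
                                                       presence_count = integer(0)),
                             removed_listed = character(0),
                             retained = character(0)) {
  structure(list(removed_rare = removed_rare,
                 removed_listed = removed_listed,
                 retained = retained),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("exclusion_report:", nrow(x$removed_rare), "rare species removed,",
      length(x$removed_listed), "removed by name,",
      length(x$retained), "retained\n")
  invisible(x)
}

#' Remove rarely recorded species
#'
#' Species with fewer presences than `min_presences` (strictly) are dropped;
#' rare species carry too few positive examples to support a reliable
#' presence/absence model.
#'
#' @param data a [survey_dataset()].
#' @param min_presences minimum presence count a species must reach to be
#'   retained (default 10; the strict `<` threshold means exactly 10
#'   presences is kept).
#' @return A list with elements `data` (the reduced dataset) and `report`
#'   (an exclusion report listing removals with their presence counts).
#' @export
filter_rare_species <- function(data, min_presences = 10) {
  validate_survey(data)
  counts <- colSums(data$occurrence)
  drop <- counts < min_presences
  report <- exclusion_report(
    removed_rare = data.frame(species = data$species_names[drop],
                              presence_count = as.integer(counts[drop]),
                              row.names = NULL),
    retained = data$species_names[!drop])
  out <- survey_dataset(
    occurrence = data$occurrence[, !drop, drop = FALSE],
    environment = data$environment,
    site_ids = data$site_ids,
    species_names = data$species_names[!drop],
    env_names = data$env_names,
    normalized = data$normalized,
    norm_params = data$norm_params)
  list(data = out, report = report)
}

#' Remove species by name
#'
#' Drops species regardless of rarity, e.g. taxa whose occurrence reflects
#' stocking programmes rather than environmental suitability.
#'
#' @param data a [survey_dataset()].
#' @param names species to remove; all must be present in the dataset.
#' @return A list with elements `data` and `report`.
#' @export
exclude_species <- function(data, names) {
  validate_survey(data)
  unknown <- setdiff(names, data$species_names)
  if (length(unknown)) {
    stop("unknown species: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- !(data$species_names %in% names)
  report <- exclusion_report(removed_listed = as.character(names),
                             retained = data$species_names[keep])
  out <- survey_dataset(
    occurrence = data$occurrence[, keep, drop = FALSE],
    environment = data$environment,
    site_ids = data$site_ids,
    species_names = data$species_names[keep],
    env_names = data$env_names,
    normalized = data$normalized,
    norm_params = data$norm_params)
  list(data = out, report = report)
}

#' Min-max normalize environmental variables to \[0, 1\]
#'
#' Each variable is mapped by `(x - min) / (max - min)`. By default ("global"
#' mode) the observed per-variable minima and maxima are used; supplying
#' `params` (e.g. ranges learned on training folds) reuses stored ranges, and
#' values falling outside a supplied range are clipped to \[0, 1\].
#'
#' @param data an unnormalized [survey_dataset()].
#' @param params optional data frame with columns `variable`, `min`, `max`
#'   (as stored in `norm_params`), or a named list of `c(min, max)` pairs.
#' @return A normalized [survey_dataset()] with `norm_params` recorded.
#' @export
normalize_environment <- function(data, params = NULL) {
  validate_survey(data)
  if (data$normalized) {
    stop("dataset is already normalized", call. = FALSE)
  }
  if (is.null(params)) {
    mins <- apply(data$environment, 2, min)
    maxs <- apply(data$environment, 2, max)
    flat <- data$env_names[maxs <= mins]
    if (length(flat)) {
      stop("degenerate range (constant variable): ",
           paste(flat, collapse = ", "), call. = FALSE)
    }
    clip <- FALSE
  } else {
    if (is.list(params) && !is.data.frame(params)) {
      params <- data.frame(variable = names(params),
                           min = vapply(params, `[`, numeric(1), 1),
                           max = vapply(params, `[`, numeric(1), 2))
    }
    missing_vars <- setdiff(data$env_names, params$variable)
    if (length(missing_vars)) {
      stop("normalization params missing for: ",
           paste(missing_vars, collapse = ", "), call. = FALSE)
    }
    i <- match(data$env_names, params$variable)
    mins <- params$min[i]
    maxs <- params$max[i]
    if (any(maxs <= mins)) {
      stop("degenerate range in supplied params for: ",
           paste(data$env_names[maxs <= mins], collapse = ", "),
           call. = FALSE)
    }
    clip <- TRUE
  }
  scaled <- sweep(sweep(data$environment, 2, mins, `-`), 2, maxs - mins, `/`)
  if (clip) scaled <- pmin(pmax(scaled, 0), 1)
  survey_dataset(
    occurrence = data$occurrence,
    environment = scaled,
    site_ids = data$site_ids,
    species_names = data$species_names,
    env_names = data$env_names,
    normalized = TRUE,
    norm_params = data.frame(variable = data$env_names,
                             min = unname(mins), max = unname(maxs)))
}

#' Convert stream velocity to the semi-quantitative field score
#'
#' Field surveys record stream velocity as a 0-5 score: 0 still waters,
#' 1 about 5-6 cm/s, 2 up to 30 cm/s, 3 up to 50 cm/s, 4 up to 100 cm/s,
#' 5 above 100 cm/s. Each class's upper bound is inclusive, so the score is
#' a total function of any non-negative velocity.
#'
#' @param velocity_cm_s non-negative velocities in cm/s (vectorized).
#' @return Integer scores in 0-5.
#' @export
velocity_to_score <- function(velocity_cm_s) {
  if (!is.numeric(velocity_cm_s) || any(!is.finite(velocity_cm_s))) {
    stop("velocity must be finite and numeric", call. = FALSE)
  }
  if (any(velocity_cm_s < 0)) {
    stop("velocity must be non-negative", call. = FALSE)
  }
  breaks <- c(-Inf, 5, 6, 30, 50, 100, Inf)
  # [0,5) -> 0, [5,6] -> 1, (6,30] -> 2, (30,50] -> 3, (50,100] -> 4, >100 -> 5
  score <- as.integer(cut(velocity_cm_s, breaks = breaks, right = TRUE,
                          labels = FALSE)) - 1L
  score[velocity_cm_s < 5] <- 0L
  score[velocity_cm_s >= 5 & velocity_cm_s <= 6] <- 1L
  score
}

#' Stratified fold assignment for cross-validation
#'
#' Sites are partitioned into `k` folds preserving the target species'
#' presence/absence ratio: within each class, sites are shuffled under the
#' seed and dealt round-robin, so per-fold presence counts differ by at most
#' one from proportional allocation.
#'
#' @param data a [survey_dataset()].
#' @param target target species name.
#' @param k number of folds (default 5).
#' @param seed integer seed; the same seed reproduces the assignment.
#' @return Integer vector of fold labels (1..k), named by site id.
#' @export
stratified_folds <- function(data, target, k = 5, seed = 1) {
  validate_survey(data)
  if (!target %in% data$species_names) {
    stop("unknown target species: ", target, call. = FALSE)
  }
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  y <- data$occurrence[, target]
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      if (length(idx) < k) {
        stop("class ", cls, " has only ", length(idx),
             " sites; cannot stratify into ", k, " folds", call. = FALSE)
      }
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  names(fold) <- data$site_ids
  fold
}
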