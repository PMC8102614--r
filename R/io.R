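#' Read a per-yawn event table
#'
#' Reads a CSV of individual yawn events. Columns are located by name
#' (case-insensitive substring match): one naming the species, one the
#' individual, one the duration in seconds, and optionally a source.
#' Rows with a missing, non-numeric or non-positive duration are rejected
#' and recorded in the `"rejected"` attribute rather than silently dropped.
#'
#' @param path Path to a comma-separated, UTF-8 encoded file with a header.
#' @return A tibble with columns `species`, `individual`, `duration`
#'   (seconds) and `source`, one row per accepted yawn. Rejected rows are
#'   attached as `attr(, "rejected")`.
#' @export
read_yawn_events <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(raw) == 0L) {
    abort(paste0("no rows in yawn event file: ", path),
          class = "phyloyawn_empty_input")
  }
  sp <- find_column(raw, "species")
  ind <- find_column(raw, "individual")
  dur <- find_column(raw, "duration")
  src <- tryCatch(find_column(raw, "source"), error = function(e) NULL)
  out <- tibble(
    species = as.character(raw[[sp]]),
    individual = as.character(raw[[ind]]),
    duration = suppressWarnings(as.numeric(raw[[dur]])),
    source = if (is.null(src)) NA_character_ else as.character(raw[[src]])
  )
  bad <- !is.finite(out$duration) | out$duration <= 0 |
    !nzchar(out$species) | !nzchar(out$individual)
  rejected <- out[bad, , drop = FALSE]
  out <- out[!bad, , drop = FALSE]
  if (nrow(rejected) > 0L) {
    message(nrow(rejected), " event row(s) rejected (non-positive or ",
            "non-numeric duration, or empty identifiers)")
  }
  attr(out, "rejected") <- rejected
  out
}

find_column <- function(df, what) {
  hit <- grep(what, names(df), ignore.case = TRUE)
  if (length(hit) == 0L) {
    stop_format(paste0("required column matching '", what,
                       "' not found (columns: ",
                       paste(names(df), collapse = ", "), ")"))
  }
  names(df)[hit[1L]]
}

#' Read a species trait table
#'
#' Reads per-species body mass, brain mass and/or endocranial volume, and
#' neuron counts. Each species must have at least one of `brain_mass` /
#' `ecv`; all masses and counts must be positive where present.
#'
#' @param path CSV path with columns `species`, `clade`, and optionally
#'   `order`, `body_mass` (g), `brain_mass` (g), `ecv` (ml),
#'   `total_neurons`, `cortex_neurons`.
#' @return A tibble, one row per species.
#' @export
read_species_traits <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(raw) == 0L) {
    abort(paste0("no rows in trait file: ", path),
          class = "phyloyawn_empty_input")
  }
  for (col in c("species", "clade", "body_mass")) {
    if (!col %in% names(raw)) {
      stop_format(paste0("required column '", col, "' not found in ", path))
    }
  }
  opt <- function(col) if (col %in% names(raw)) as.numeric(raw[[col]]) else NA_real_
  out <- tibble(
    species = as.character(raw$species),
    clade = tolower(as.character(raw$clade)),
    order = if ("order" %in% names(raw)) as.character(raw$order) else NA_character_,
    body_mass = as.numeric(raw$body_mass),
    brain_mass = opt("brain_mass"),
    ecv = opt("ecv"),
    total_neurons = opt("total_neurons"),
    cortex_neurons = opt("cortex_neurons")
  )
  if (any(is.na(out$brain_mass) & is.na(out$ecv))) {
    bad <- out$species[is.na(out$brain_mass) & is.na(out$ecv)]
    stop_format(paste0("species without brain_mass or ecv: ",
                       paste(bad, collapse = ", ")))
  }
  num <- c("body_mass", "brain_mass", "ecv", "total_neurons", "cortex_neurons")
  for (col in num) {
    v <- out[[col]]
    if (any(!is.na(v) & v <= 0)) {
      stop_format(paste0("non-positive values in '", col, "' for: ",
                         paste(out$species[!is.na(v) & v <= 0], collapse = ", ")))
    }
  }
  out
}

#' Convert endocranial volume to brain mass
#'
#' Applies the standard allometric conversion brain mass (g) =
#' 1.036 x ECV (ml), used when a direct brain mass measurement is
#' unavailable.
#'
#' @param ecv Endocranial volume in millilitres (positive).
#' @return Brain mass in grams.
#' @export
ecv_to_brain_mass <- function(ecv) {
  if (any(!is.finite(ecv)) || any(ecv <= 0)) {
    stop_domain("ecv must be positive and finite")
  }
  1.036 * ecv
}

#' Aggregate yawn events into a species-level trait table
#'
#' Computes per-species mean yawn duration and merges species traits,
#' applying the retention filters: a species is kept only if it has at
#' least `min_yawns` yawns from at least `min_individuals` distinct
#' individuals, and is not on the explicit exclusion list (used for
#' domesticated species whose brain measures and tree placement are
#' unreliable). Brain mass prefers the direct measurement; ECV is
#' converted otherwise. Neuronal density is total neurons per gram of
#' brain, computed before the log transform. Log-scale measures are
#' z-standardized within clade.
#'
#' @param events Tibble from [read_yawn_events()].
#' @param traits Tibble from [read_species_traits()].
#' @param exclude Character vector of species to drop explicitly.
#' @param min_yawns,min_individuals Retention thresholds (default 2 and 2).
#' @param mean_over `"yawns"` (default) averages all yawns per species;
#'   `"individuals"` averages individual means.
#' @return A tibble with one row per retained species: `species`, `clade`,
#'   `order`, `mean_duration`, `n_yawns`, `n_individuals`, raw and
#'   log-scale trait columns, and within-clade z-scores (`z_log_brain`,
#'   ...). The drop log (species, reason) is in `attr(, "drop_log")` and
#'   unmatched event species in `attr(, "unmatched")`.
#' @export
aggregate_species <- function(events, traits, exclude = character(),
                              min_yawns = 2L, min_individuals = 2L,
                              mean_over = c("yawns", "individuals")) {
  mean_over <- match.arg(mean_over)
  events$.key <- canonicalize_species(events$species)
  traits$.key <- canonicalize_species(traits$species)
  exclude_key <- canonicalize_species(exclude)

  unmatched <- events |>
    filter(!.data$.key %in% traits$.key) |>
    group_by(.data$species) |>
    summarise(n_yawns = dplyr::n(), .groups = "drop")
  if (nrow(unmatched) > 0L) {
    message("events for ", nrow(unmatched),
            " species not present in the trait table: ",
            paste(unmatched$species, collapse = ", "))
  }
  events <- filter(events, .data$.key %in% traits$.key)

  per_sp <- events |>
    group_by(.data$.key) |>
    summarise(
      n_yawns = dplyr::n(),
      n_individuals = n_distinct(.data$individual),
      mean_yawns = mean(.data$duration),
      mean_individuals = mean(tapply(.data$duration, .data$individual, mean)),
      .groups = "drop"
    ) |>
    mutate(mean_duration = if (mean_over == "yawns") .data$mean_yawns
           else .data$mean_individuals)

  drop_log <- tibble(species = character(), reason = character())
  log_drop <- function(keys, reason) {
    sp <- traits$species[match(keys, traits$.key)]
    sp[is.na(sp)] <- keys[is.na(sp)]
    bind_rows(drop_log, tibble(species = sp, reason = reason))
  }

  fail_filter <- per_sp$.key[per_sp$n_yawns < min_yawns |
                             per_sp$n_individuals < min_individuals]
  if (length(fail_filter)) {
    drop_log <- log_drop(fail_filter, sprintf(
      "fewer than %d yawns from %d individuals", min_yawns, min_individuals))
  }
  per_sp <- per_sp[!per_sp$.key %in% fail_filter, , drop = FALSE]

  excluded <- intersect(per_sp$.key, exclude_key)
  if (length(excluded)) drop_log <- log_drop(excluded, "explicitly excluded")
  per_sp <- per_sp[!per_sp$.key %in% exclude_key, , drop = FALSE]

  out <- traits |>
    dplyr::inner_join(select(per_sp, ".key", "n_yawns", "n_individuals",
                             "mean_duration"), by = ".key") |>
    mutate(
      brain_mass = ifelse(!is.na(.data$brain_mass), .data$brain_mass,
                          1.036 * .data$ecv),
      neuron_density = .data$total_neurons / .data$brain_mass,
      log_body = log(.data$body_mass),
      log_brain = log(.data$brain_mass),
      log_total_neurons = log(.data$total_neurons),
      log_cortex_neurons = log(.data$cortex_neurons),
      log_neuron_density = log(.data$neuron_density)
    ) |>
    select(-".key")

  for (col in c("log_body", "log_brain", "log_total_neurons",
                "log_cortex_neurons", "log_neuron_density")) {
    out[[paste0("z_", col)]] <- stats::ave(
      out[[col]], out$clade,
      FUN = function(v) {
        ok <- is.finite(v)
        if (sum(ok) < 2L || sd(v[ok]) == 0) return(rep(NA_real_, length(v)))
        (v - mean(v[ok])) / sd(v[ok])
      })
  }
  out <- as_tibble(out)
  attr(out, "drop_log") <- drop_log
  attr(out, "unmatched") <- unmatched
  out
}

#' Retrieve the drop log of an aggregated species table
#' @param x A table from [aggregate_species()].
#' @return Tibble of dropped species and reasons.
#' @export
drop_log <- function(x) attr(x, "drop_log") %||% tibble(species = character(),
                                                        reason = character())

#' Write the drop log and unmatched report as JSON
#' @param x A table from [aggregate_species()].
#' @param path Output path.
#' @export
write_drop_log <- function(x, path) {
  jsonlite::write_json(
    list(dropped = drop_log(x),
         unmatched = attr(x, "unmatched") %||% tibble()),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Match a species table to a phylogeny
#'
#' Prunes the tree to the species in the table (exact match after
#' canonicalization: trimmed, whitespace collapsed to underscores,
#' case-insensitive) and reorders the table to tip order. Species absent
#' from the tree are dropped with a logged reason.
#'
#' @param data Species-level tibble with a `species` column.
#' @param tree A rooted `phylo` tree with branch lengths.
#' @return A list with elements `data` (reordered tibble), `tree` (pruned
#'   `phylo`), and `dropped` (tibble of species not on the tree).
#' @export
match_tree <- function(data, tree) {
  if (!inherits(tree, "phylo")) stop_domain("tree must be a 'phylo' object")
  key_data <- canonicalize_species(data$species)
  key_tip <- canonicalize_species(tree$tip.label)
  if (anyDuplicated(key_tip)) stop_domain("tree tip labels are not unique")
  keep <- key_data %in% key_tip
  dropped <- tibble(species = data$species[!keep], reason = "not in tree")
  if (nrow(dropped) > 0L) {
    message(nrow(dropped), " species dropped (not in tree): ",
            paste(dropped$species, collapse = ", "))
  }
  data <- data[keep, , drop = FALSE]
  key_data <- key_data[keep]
  if (nrow(data) < 4L) {
    abort("fewer than 4 species matched to the tree; the phylogenetic model is unidentifiable",
          class = "phyloyawn_insufficient_data")
  }
  tree <- ape::keep.tip(tree, tree$tip.label[key_tip %in% key_data])
  ord <- match(canonicalize_species(tree$tip.label), key_data)
  data <- data[ord, , drop = FALSE]
  list(data = as_tibble(data), tree = tree, dropped = dropped)
}
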