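#' Default predator--prey pairs
#'
#' The five pairs analysed by default: fox against hare, rabbit and wood
#' mouse, and pine marten against squirrel and wood mouse. Fully overridable
#' in \code{\link{analysis_config}}.
#'
#' @return list of length-2 character vectors (predator, prey).
#' @export
default_pairs <- function() {
  list(c("fox", "hare"), c("fox", "rabbit"), c("fox", "wood_mouse"),
       c("pine_marten", "squirrel"), c("pine_marten", "wood_mouse"))
}

#' Analysis configuration
#'
#' Bundles every tunable of the end-to-end analysis. \code{species_groups}
#' pools species before analysis (e.g. the two hare and two squirrel species
#' into "hare" and "squirrel").
#'
#' @param detections detection data.frame, or path to a detection CSV.
#' @param sites site table, or path to a site CSV.
#' @param pairs list of (predator, prey) pairs (default
#'   \code{\link{default_pairs}}).
#' @param species_groups named character vector mapping raw species labels to
#'   pooled labels, or NULL.
#' @param independence_interval hours (default 1).
#' @param location_key co-occurrence unit: \code{"site_id"} (default) or
#'   \code{"camera_id"}.
#' @param estimator overlap estimator (\code{"auto"}, \code{"dhat1"},
#'   \code{"dhat4"}).
#' @param bootstrap_reps bootstrap resamples for overlap CIs (default 1000).
#' @param tails 1 (default) or 2 for the CCF significance rule.
#' @param dominance dominance factor for the cathemeral call (default 1.25).
#' @param seed integer seed controlling the bootstrap.
#' @param schema detection column mapping (see \code{\link{default_schema}}).
#' @return an \code{analysis_config} list.
#' @export
analysis_config <- function(detections, sites, pairs = default_pairs(),
                            species_groups = default_species_groups(),
                            independence_interval = 1,
                            location_key = "site_id",
                            estimator = "auto", bootstrap_reps = 1000,
                            tails = 1, dominance = 1.25, seed = 1,
                            schema = default_schema()) {
  structure(list(detections = detections, sites = sites, pairs = pairs,
                 species_groups = species_groups,
                 independence_interval = independence_interval,
                 location_key = location_key, estimator = estimator,
                 bootstrap_reps = bootstrap_reps, tails = tails,
                 dominance = dominance, seed = seed, schema = schema),
            class = "analysis_config")
}

#' Default species pooling
#'
#' Pools the two hare species into "hare" and the two squirrel species into
#' "squirrel", matching how congeners with indistinguishable activity are
#' usually grouped.
#'
#' @return named character vector (raw label -> pooled label).
#' @export
default_species_groups <- function() {
  c(irish_hare = "hare", european_hare = "hare",
    grey_squirrel = "squirrel", red_squirrel = "squirrel")
}

#' Read an analysis configuration from YAML
#'
#' Keys mirror the arguments of \code{\link{analysis_config}};
#' \code{detections} and \code{sites} are file paths, \code{pairs} a list of
#' two-element lists, \code{schema} and \code{species_groups} maps.
#'
#' @param path YAML file.
#' @return an \code{analysis_config}.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(detections = y$detections, sites = y$sites)
  if (!is.null(y$pairs)) args$pairs <- lapply(y$pairs, unlist)
  if (!is.null(y$species_groups)) args$species_groups <- unlist(y$species_groups)
  if (!is.null(y$schema)) args$schema <- unlist(y$schema)
  for (k in c("independence_interval", "location_key", "estimator",
              "bootstrap_reps", "tails", "dominance", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(analysis_config, args)
}

seasons_all <- c("annual", "spring", "summer", "autumn", "winter")

#' Run the full diel-activity analysis
#'
#' Executes the whole pipeline: read/validate, independence filtering, solar
#' annotation, per-species detection summaries, diel classification, seasonal
#' offset ANOVA, and per-pair overlap (with bootstrap CIs) and lagged
#' cross-correlation, annually and per season. Deterministic given the
#' config seed. Seasons in which a pair member has too few detections are
#' skipped with a logged note.
#'
#' @param config an \code{\link{analysis_config}}.
#' @param quiet suppress progress messages (default TRUE).
#' @return a \code{report_bundle}: list of data.frames \code{summary},
#'   \code{classification}, \code{seasonal_anova}, \code{overlap},
#'   \code{ccf}, plus \code{notes} (character log) and \code{events} (the
#'   annotated independent events).
#' @export
run_all <- function(config, quiet = TRUE) {
  notes <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    notes <<- c(notes, msg)
    if (!quiet) message(msg)
  }
  det <- config$detections
  if (is.character(det)) det <- read_detections(det, config$schema)
  sites <- config$sites
  if (is.character(sites)) sites <- read_sites(sites)

  if (!is.null(config$species_groups)) {
    grp <- config$species_groups[det$species]
    det$species <- ifelse(is.na(grp), det$species, grp)
  }
  raw <- det
  det <- filter_independent(det, config$independence_interval)
  say("independence filter (", config$independence_interval, " h): ",
      nrow(raw), " raw -> ", nrow(det), " independent events")
  ev <- annotate_solar(as.data.frame(det), sites)
  species <- sort(unique(ev$species))
  for (pr in config$pairs)
    for (sp in pr) if (!sp %in% species)
      warning("pair species not present in data: ", sp)

  smry <- as.data.frame.matrix(table(ev$species, ev$season))
  smry <- data.frame(species = rownames(smry), smry,
                     total = rowSums(smry), row.names = NULL)

  cls <- do.call(rbind, lapply(species, function(sp) {
    lab <- classify_diel(ev[ev$species == sp, ], dominance = config$dominance)
    r <- attr(lab, "rates")
    data.frame(species = sp, class = as.character(lab),
               rate_nocturnal = r[["nocturnal"]], rate_diurnal = r[["diurnal"]],
               rate_crepuscular = r[["crepuscular"]])
  }))

  anova_rows <- list(); tukey_rows <- list()
  for (sp in species) {
    e <- ev[ev$species == sp, ]
    res <- tryCatch(anova_offsets(e$offset, e$season, species = sp),
                    error = function(err) {
                      say("seasonal ANOVA skipped for ", sp, ": ",
                          conditionMessage(err))
                      NULL
                    })
    if (is.null(res)) next
    anova_rows[[sp]] <- data.frame(species = sp, F = res$F,
                                   df_between = res$df[["between"]],
                                   df_within = res$df[["within"]], p = res$p)
    tukey_rows[[sp]] <- data.frame(species = sp, res$tukey)
  }

  set.seed(config$seed)
  ov_rows <- list(); ccf_rows <- list()
  for (pr in config$pairs) {
    if (!all(pr %in% species)) next
    co <- restrict_to_cooccurrence(ev, pr[1], pr[2], config$location_key)
    for (ssn in seasons_all) {
      sub <- if (ssn == "annual") co else co[co$season == ssn, , drop = FALSE]
      ta <- hours_to_radians(clock_hours(sub$timestamp[sub$species == pr[1]]))
      tb <- hours_to_radians(clock_hours(sub$timestamp[sub$species == pr[2]]))
      if (length(ta) < 10 || length(tb) < 10) {
        say("skipping ", pr[1], "-", pr[2], " in ", ssn,
            ": too few detections (", length(ta), ", ", length(tb), ")")
        next
      }
      ov <- overlap_analysis(ta, tb, pair = pr, season = ssn,
                             estimator = config$estimator,
                             reps = config$bootstrap_reps)
      ov_rows[[length(ov_rows) + 1]] <- data.frame(
        predator = pr[1], prey = pr[2], season = ssn,
        delta_pct = round(100 * ov$delta),
        ci_low_pct = round(100 * ov$ci95[1]),
        ci_high_pct = round(100 * ov$ci95[2]),
        category = ov$category, estimator = ov$estimator,
        n_predator = ov$n_a, n_prey = ov$n_b, delta = ov$delta)
      px <- bin_hourly(sub, species = pr[1])
      py <- bin_hourly(sub, species = pr[2])
      cc <- tryCatch(
        summarise_ccf(circular_ccf(px$counts, py$counts),
                      t_crit = critical_t(0.05, 22, config$tails)),
        error = function(err) {
          say("skipping CCF for ", pr[1], "-", pr[2], " in ", ssn, ": ",
              conditionMessage(err))
          NULL
        })
      if (is.null(cc)) next
      if (nrow(cc$ranges)) {
        for (k in seq_len(nrow(cc$ranges))) {
          in_run <- cc$lags >= cc$ranges$from[k] & cc$lags <= cc$ranges$to[k]
          best <- which(in_run)[order(-abs(cc$r[in_run]))][1]
          ccf_rows[[length(ccf_rows) + 1]] <- data.frame(
            predator = pr[1], prey = pr[2], season = ssn,
            from = cc$ranges$from[k], to = cc$ranges$to[k],
            peak_lag = cc$lags[best], t = abs(cc$t[best]), r = cc$r[best],
            stars = significance_stars(cc$t[best]))
        }
      } else {
        ccf_rows[[length(ccf_rows) + 1]] <- data.frame(
          predator = pr[1], prey = pr[2], season = ssn,
          from = NA_integer_, to = NA_integer_, peak_lag = NA_integer_,
          t = NA_real_, r = NA_real_, stars = "")
      }
    }
  }

  empty_ov <- data.frame(predator = character(), prey = character(),
                         season = character(), delta_pct = numeric(),
                         ci_low_pct = numeric(), ci_high_pct = numeric(),
                         category = character(), estimator = character(),
                         n_predator = integer(), n_prey = integer(),
                         delta = numeric())
  structure(list(
    summary = smry,
    classification = cls,
    seasonal_anova = if (length(anova_rows)) do.call(rbind, anova_rows) else NULL,
    tukey = if (length(tukey_rows)) do.call(rbind, tukey_rows) else NULL,
    overlap = if (length(ov_rows)) do.call(rbind, ov_rows) else empty_ov,
    ccf = if (length(ccf_rows)) do.call(rbind, ccf_rows) else NULL,
    notes = notes, events = ev
  ), class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n  species:", nrow(x$summary),
      "| overlap rows:", nrow(x$overlap),
      "| ccf rows:", if (is.null(x$ccf)) 0 else nrow(x$ccf), "\n")
  invisible(x)
}

#' Write the report bundle as CSV files
#'
#' Writes \code{summary.csv} (detections by species and season),
#' \code{classification.csv}, \code{seasonal_anova.csv}, \code{tukey.csv},
#' \code{overlap.csv} (pair, season, overlap \% with CI and category) and
#' \code{ccf.csv} (pair, season, lag range, peak lag, t, r, stars), plus the
#' run log \code{notes.txt}.
#'
#' @param bundle a \code{report_bundle} from \code{\link{run_all}}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_reports <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df))
      utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wr(bundle$summary, "summary.csv")
  wr(bundle$classification, "classification.csv")
  wr(bundle$seasonal_anova, "seasonal_anova.csv")
  wr(bundle$tukey, "tukey.csv")
  wr(bundle$overlap, "overlap.csv")
  wr(bundle$ccf, "ccf.csv")
  writeLines(bundle$notes, file.path(dir, "notes.txt"))
  invisible(dir)
}
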