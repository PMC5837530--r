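#' Default pipeline configuration
#'
#' Returns the full configuration list understood by
#' \code{\link{runPipeline}}; any element may be overridden via \code{...}
#' (shallow-merged per block). The default cohort (12 cases, 8 controls on a
#' 48^3 grid) keeps an end-to-end run on one CPU within minutes.
#'
#' @param ... named blocks to override (e.g. cohort = list(nCase = 4)).
#' @return configuration list.
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    outDir = NULL,
    writeImages = FALSE,
    excludeLesions = FALSE,
    stages = c("simulate", "register", "jd", "summarize", "voxelwise",
               "cohort-stats", "power"),
    phantom = list(gridShape = c(48L, 48L, 48L), voxelSizeMm = 3,
                   corticalFoldCount = 8L, noiseSd = 1.5,
                   scannerBias = 0.05),
    atrophy = list(),
    cohort = list(nCase = 12L, nControl = 8L),
    registration = list(levels = 3L, iterations = c(50L, 50L, 25L),
                        fluidSigmaMm = 2, diffusionSigmaMm = 1,
                        squaringSteps = 6L, imageFwhmMm = 7),
    inference = list(m = 200L, alpha = 0.05, fwhmMm = 8,
                     covariates = c("age_years", "sex", "scanner",
                                    "icv_mm3"),
                     tfce = list(E = 0.5, H = 2, nSteps = 50L,
                                 connectivity = 26L)),
    power = list(te = 0.25))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      for (k in names(over[[nm]])) cfg[[nm]][[k]] <- over[[nm]][[k]]
    } else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file; blocks merge over \code{\link{defaultConfig}}.
#' @return configuration list.
#' @export
readConfig <- function(path) {
  do.call(defaultConfig, yaml::read_yaml(path))
}

# FNV-1a hash of the deparsed configuration (hex string).
configHash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  h <- 2166136261
  for (v in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), v)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the longitudinal morphometry pipeline
#'
#' Executes simulate -> register -> jd -> summarize -> voxelwise ->
#' cohort-stats -> power (any contiguous sub-span selectable via
#' \code{config$stages}). Later stages consume the \code{state} produced by
#' earlier ones, so a sub-span starting after \code{simulate} needs the state
#' of a previous call (e.g. precomputed JD maps). The run is deterministic
#' given the configuration and master seed. When \code{config$outDir} is set,
#' summary CSVs, result JSON and (optionally) NIfTI volumes are written and
#' listed in the returned manifest.
#'
#' @param config list from \code{\link{defaultConfig}} or
#'   \code{\link{readConfig}}.
#' @param state optional state list from a previous (partial) run.
#' @return list: \code{record} (config hash, version, per-stage timings,
#'   warnings, file manifest), \code{state} (intermediate objects),
#'   \code{results} (stats and power outputs).
#' @export
runPipeline <- function(config = defaultConfig(), state = list()) {
  allStages <- c("simulate", "register", "jd", "summarize", "voxelwise",
                 "cohort-stats", "power")
  stages <- match.arg(config$stages, allStages, several.ok = TRUE)
  idx <- sort(match(stages, allStages))
  if (any(diff(idx) != 1)) stop("stages must form a contiguous span")
  stages <- allStages[idx]

  record <- list(configHash = configHash(
                   config[setdiff(names(config), "outDir")]),
                 version = as.character(utils::packageVersion("longdbm")),
                 timings = list(), warnings = character(),
                 manifest = character())
  results <- list()
  outDir <- config$outDir
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  emit <- function(paths) record$manifest <<- c(record$manifest, paths)
  note <- function(w) record$warnings <<- c(record$warnings, w)
  stageTime <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    record$timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  phantom <- do.call(phantomSpec,
                     c(config$phantom, list(seed = config$seed)))
  atrophy <- do.call(atrophySpec, config$atrophy)

  if ("simulate" %in% stages) {
    state$sim <- stageTime("simulate",
      simulateCohort(config$cohort$nCase, config$cohort$nControl,
                     atrophy, phantom, seed = config$seed,
                     makeImages = TRUE))
    if (!is.null(outDir)) {
      p <- file.path(outDir, "cohort.csv")
      writeCohort(state$sim$cohort, p)
      emit(p)
      if (isTRUE(config$writeImages)) {
        for (id in state$sim$cohort$id) {
          pb <- file.path(outDir, paste0(id, "_baseline.nii.gz"))
          pf <- file.path(outDir, paste0(id, "_followup.nii.gz"))
          writeVolume(state$sim$pairs[[id]]$baseline, pb)
          writeVolume(state$sim$pairs[[id]]$followup, pf)
          emit(c(pb, pf))
        }
      }
    }
  }

  if ("register" %in% stages) {
    if (is.null(state$sim)) stop("stage 'register' needs simulated pairs")
    params <- do.call(registrationParams, config$registration)
    state$warps <- stageTime("register", {
      lapply(state$sim$cohort$id, function(id) {
        pr <- state$sim$pairs[[id]]
        reg <- registerSymmetric(pr$baseline, pr$followup, params)
        if (!reg$improved)
          note(paste0("subject ", id, ": registration kept identity"))
        reg$fullWarp
      })
    })
    names(state$warps) <- state$sim$cohort$id
  }

  if ("jd" %in% stages) {
    if (is.null(state$warps)) stop("stage 'jd' needs registration warps")
    state$jd <- stageTime("jd", {
      out <- lapply(state$sim$cohort$id, function(id) {
        jd <- withCallingHandlers(
          jacobianMap(state$warps[[id]]),
          warning = function(w) {
            note(paste0("subject ", id, ": ", conditionMessage(w)))
            invokeRestart("muffleWarning")
          })
        jd
      })
      names(out) <- state$sim$cohort$id
      out
    })
    if (!is.null(outDir) && isTRUE(config$writeImages)) {
      for (id in names(state$jd)) {
        p <- file.path(outDir, paste0(id, "_jd.nii.gz"))
        emit(writeVolume(state$jd[[id]], p))
      }
    }
  }

  if ("summarize" %in% stages) {
    if (is.null(state$jd)) stop("stage 'summarize' needs JD maps")
    state$summaries <- stageTime("summarize", {
      rows <- list(); rois <- list()
      for (i in seq_len(nrow(state$sim$cohort))) {
        rec <- state$sim$cohort[i, ]
        s <- subjectSummary(rec$id, state$jd[[rec$id]], state$sim$labels,
                            rec$interval_years)
        rows[[rec$id]] <- s$summary
        rois[[rec$id]] <- s$roi
      }
      list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
           roi = do.call(rbind, c(rois, make.row.names = FALSE)))
    })
    if (!is.null(outDir)) {
      p1 <- file.path(outDir, "subject_summaries.csv")
      p2 <- file.path(outDir, "roi_summaries.csv")
      utils::write.csv(state$summaries$summary, p1, row.names = FALSE)
      utils::write.csv(state$summaries$roi, p2, row.names = FALSE)
      emit(c(p1, p2))
    }
  }

  cohortUsed <- function() {
    co <- state$sim$cohort
    if (isTRUE(config$excludeLesions)) co[!co$lesion, , drop = FALSE] else co
  }

  if ("voxelwise" %in% stages) {
    if (is.null(state$jd)) stop("stage 'voxelwise' needs JD maps")
    results$voxelwise <- stageTime("voxelwise", {
      co <- cohortUsed()
      dims <- dim(voxelData(state$jd[[co$id[1]]]))
      stack <- array(0, c(dims, nrow(co)))
      for (i in seq_len(nrow(co))) {
        rec <- co[i, ]
        ann <- suppressWarnings(
          annualizeJd(state$jd[[rec$id]], rec$interval_years))
        sm <- smoothVolume(ann, config$inference$fwhmMm)
        stack[, , , i] <- voxelData(sm)
      }
      mask <- tissueMask(state$sim$labels, "GM") |
        tissueMask(state$sim$labels, "WM")
      co$group <- factor(co$group, levels = c("control", "case"))
      tf <- do.call(tfceParams, config$inference$tfce)
      fml <- as.formula(paste(c("~ group", config$inference$covariates),
                              collapse = " + "))
      res <- permutationCorrect(stack, co, fml,
        m = config$inference$m, seed = config$seed, tfce = tf, mask = mask)
      res$percentSignificant <- percentSignificantVoxels(
        res$pMap, mask, config$inference$alpha)
      res
    })
    if (!is.null(outDir)) {
      sp <- voxelSpacing(state$sim$labels)
      pT <- file.path(outDir, "group_tmap.nii.gz")
      pP <- file.path(outDir, "group_p_corrected.nii.gz")
      writeVolume(ScalarVolume(results$voxelwise$tMap, sp), pT)
      pm <- results$voxelwise$pMap
      pm[is.na(pm)] <- 1
      writeVolume(ScalarVolume(pm, sp), pP)
      emit(c(pT, pP))
    }
  }

  if ("cohort-stats" %in% stages) {
    if (is.null(state$summaries)) stop("stage 'cohort-stats' needs summaries")
    results$cohortStats <- stageTime("cohort-stats", {
      co <- cohortUsed()
      sm <- state$summaries$summary[state$summaries$summary$id %in% co$id, ]
      roi <- state$summaries$roi[state$summaries$roi$id %in% co$id, ]
      groupFits <- lapply(c(gm = "mean_jd_gm", wm = "mean_jd_wm"),
                          function(oc) fitGroupAdjusted(sm, co, oc))
      df <- merge(sm, co, by = "id")
      parts <- lapply(c(gm = "mean_jd_gm", wm = "mean_jd_wm"), function(oc) {
        hierarchicalPartition(df[[oc]],
          data.frame(group = factor(df$group), age = df$age_years,
                     sex = factor(df$sex), scanner = factor(df$scanner)))
      })
      sulcal <- fitSulcalInteraction(roi, co)
      trueGm <- vapply(co$id, function(id)
        mean(state$sim$truth[[id]]$annualJd@data[
          tissueMask(state$sim$labels, "GM")]), numeric(1))
      panel <- simulateNeuropsych(co, trueGm,
                                  seed = deriveSeed(config$seed, "npsych"))
      corrs <- neuropsychCorrelations(panel, sm)
      change <- tryCatch(scoreChangeModels(panel), error = function(e) {
        note(paste0("score change models skipped: ", conditionMessage(e)))
        NULL
      })
      list(groupFits = groupFits, partitions = parts, sulcal = sulcal,
           neuropsych = corrs, scoreChange = change)
    })
  }

  if ("power" %in% stages) {
    if (is.null(state$summaries)) stop("stage 'power' needs summaries")
    results$power <- stageTime("power", {
      co <- cohortUsed()
      df <- merge(state$summaries$summary, co, by = "id")
      measures <- c(rate_gm = "rate_gm", rate_wm = "rate_wm",
                    rate_brain = "rate_brain", jd_gm = "mean_jd_gm",
                    jd_wm = "mean_jd_wm", jd_brain = "mean_jd_brain")
      te <- config$power$te
      tab <- lapply(names(measures), function(nm) {
        x <- df[[measures[[nm]]]]
        g <- df$group
        es <- cohensD(mean(x[g == "case"]), sd(x[g == "case"]),
                      sum(g == "case"),
                      mean(x[g == "control"]), sd(x[g == "control"]),
                      sum(g == "control"))
        data.frame(measure = nm, d = es$d, ci_lo = es$ci[1],
                   ci_hi = es$ci[2],
                   n_per_arm = sampleSizePerArm(te, abs(es$d)),
                   stringsAsFactors = FALSE)
      })
      list(table = do.call(rbind, tab), te = te)
    })
    if (!is.null(outDir)) {
      p <- file.path(outDir, "power_table.csv")
      utils::write.csv(results$power$table, p, row.names = FALSE)
      emit(p)
    }
  }

  if (!is.null(outDir)) {
    p <- file.path(outDir, "run_record.json")
    jsonlite::write_json(record[c("configHash", "version", "timings",
                                  "warnings", "manifest")],
                         p, auto_unbox = TRUE, digits = NA)
    record$manifest <- c(record$manifest, p)
  }

  list(record = record, state = state, results = results)
}
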