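#' Resolve a pipeline run configuration
#'
#' Fills a run configuration (a named list or a YAML file of key/values) with
#' package defaults. Keys: \code{segments}, \code{clinical} (input paths; both
#' may be omitted when \code{simulate} is given), \code{simulate} (a list of
#' [cohortSpec()] argument overrides), \code{gene_bed}, \code{gene_sets}
#' (optional annotation paths), \code{contrasts}, \code{modality_sets}
#' (e.g. \code{list("L", "N", "L,N,F")}), \code{delta_grid}
#' (from/to/by in log10 bp), \code{cv_repeats}, \code{cv_trim},
#' \code{truncation}, \code{u_test_draws}, \code{seed}, \code{outdir}.
#'
#' @param config Named list or path to a YAML file.
#' @return The resolved configuration list.
#' @export
resolveConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- list(segments = NULL, clinical = NULL, simulate = NULL,
              gene_bed = NULL, gene_sets = NULL,
              contrasts = c("recurrence", "fast", "lethal"),
              modality_sets = list("L", "N", "F", "G", "L,N,F", "L,N,F,G"),
              delta_grid = list(from = 3.3, to = 6.5, by = 0.1),
              cv_repeats = 14L, cv_trim = 2L, truncation = 90,
              u_test_draws = 1e7, seed = 1L, outdir = "lsrcnv_run")
  for (k in names(config)) def[[k]] <- config[[k]]
  if (is.null(def$simulate) &&
      (is.null(def$segments) || is.null(def$clinical)))
    stop("config needs either input paths (segments + clinical) ",
         "or a 'simulate' block")
  def
}

.modalitySet <- function(s) strsplit(gsub(" ", "", s), ",")[[1]]

.manifest <- function(cfg) {
  files <- c("config.yaml", "run.log", "segments_filtered.tsv",
             "cv_metrics.csv")
  for (ct in cfg$contrasts)
    files <- c(files,
               sprintf("lsr_scores_%s.csv", ct),
               sprintf("delta_curve_%s.csv", ct),
               sprintf("survival_tests_%s.csv", ct),
               sprintf("utest_%s.csv", ct),
               sprintf("km_%s.csv", ct))
  if (!is.null(cfg$gene_bed)) {
    files <- c(files, "gene_fisher.csv", "cnv_frequency.csv")
    if (!is.null(cfg$gene_sets)) files <- c(files, "pathway_ks.csv")
  }
  c(files, "manifest.txt")
}

#' Run the full analysis pipeline
#'
#' Executes, per the configuration: cohort simulation or input reading,
#' segment filtering, per-contrast LSR threshold tuning, trimmed repeated
#' two-fold cross-validation for every modality set, cross-fitted survival
#' comparison of predicted risk groups with pairwise Monte-Carlo U tests, and
#' (when a BED is supplied) gene-level association. All outputs, the resolved
#' configuration, a manifest and a run log are written to the output
#' directory.
#'
#' @param config Named list or YAML path; see [resolveConfig()].
#' @param dryRun If TRUE, create nothing and return the output manifest.
#' @return Output directory path (invisibly), or the manifest if
#'   \code{dryRun}.
#' @export
runPipeline <- function(config = list(), dryRun = FALSE) {
  cfg <- resolveConfig(config)
  if (dryRun) return(.manifest(cfg))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(cfg$outdir, "run.log")
  logLine <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = logFile, append = TRUE, sep = "")
    message(msg)
  }
  stage <- function(name, expr) {
    logLine("stage ", name)
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  }
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))],
                   file.path(cfg$outdir, "config.yaml"))
  logLine("seed ", cfg$seed, "; lsrcnv ",
          as.character(utils::packageVersion("lsrcnv")))

  dat <- stage("input", {
    if (!is.null(cfg$simulate)) {
      spec <- do.call(cohortSpec,
                      c(cfg$simulate[setdiff(names(cfg$simulate), "seed")],
                        list(seed = cfg$seed)))
      generateCohort(spec)
    } else {
      list(segments = readSegments(cfg$segments),
           clinical = readClinical(cfg$clinical))
    }
  })
  grid <- seq(cfg$delta_grid$from, cfg$delta_grid$to, by = cfg$delta_grid$by)
  filt <- stage("filter", {
    f <- filterSegments(dat$segments)
    writeSegments(f, file.path(cfg$outdir, "segments_filtered.tsv"))
    f
  })
  profiles <- stage("profiles", buildProfiles(filt))

  cvRows <- list()
  for (ct in cfg$contrasts) {
    stage(paste0("lsr/", ct), {
      lab <- contrastLabels(dat$clinical, ct)
      keep <- !is.na(lab) & dat$clinical$sample %in% sampleIDs(profiles)
      od <- optimizeDelta(profiles[dat$clinical$sample[keep]], lab[keep],
                          grid)
      write.csv(od$curve, file.path(cfg$outdir,
                                    sprintf("delta_curve_%s.csv", ct)),
                row.names = FALSE)
      sc <- computeLSR(profiles[dat$clinical$sample[keep]], od$delta)
      write.csv(data.frame(sample = names(sc), lsr = unname(sc),
                           label = lab[keep]),
                file.path(cfg$outdir, sprintf("lsr_scores_%s.csv", ct)),
                row.names = FALSE)
    })
    survRows <- list(); kmRows <- list(); chi2s <- c()
    for (ms in cfg$modality_sets) {
      mods <- .modalitySet(ms)
      cv <- stage(paste0("cv/", ct, "/", ms),
                  trimmedCV(profiles, dat$clinical, ct, mods,
                            cfg$cv_repeats, cfg$cv_trim, cfg$seed, grid))
      cvRows[[paste(ct, ms)]] <- data.frame(
        contrast = ct, model = ms, role = c("train", "test"),
        rbind(cv@train, cv@test), row.names = NULL)
      sv <- stage(paste0("survival/", ct, "/", ms), {
        grp <- mergedCvGroups(profiles, dat$clinical, ct, mods, cfg$seed,
                              grid)
        riskGroupSurvival(grp, cfg$truncation)
      })
      chi2s[ms] <- sv$chi2
      survRows[[ms]] <- data.frame(
        contrast = ct, model = ms, chi2 = sv$chi2, logrank_p = sv$p,
        km_high = sv$survivalRates$km[1], km_low = sv$survivalRates$km[2],
        raw_high = sv$survivalRates$raw[1], raw_low = sv$survivalRates$raw[2])
      kmRows[[ms]] <- rbind(
        data.frame(model = ms, group = "high", time = sv$kmHigh@time,
                   surv = sv$kmHigh@surv),
        data.frame(model = ms, group = "low", time = sv$kmLow@time,
                   surv = sv$kmLow@surv))
    }
    write.csv(do.call(rbind, survRows),
              file.path(cfg$outdir, sprintf("survival_tests_%s.csv", ct)),
              row.names = FALSE)
    write.csv(do.call(rbind, kmRows),
              file.path(cfg$outdir, sprintf("km_%s.csv", ct)),
              row.names = FALSE)
    stage(paste0("utest/", ct), {
      nm <- names(chi2s)
      um <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
      for (i in seq_along(nm)) for (j in seq_along(nm)) if (i < j) {
        um[i, j] <- um[j, i] <-
          uTest(chi2s[i], chi2s[j], cfg$u_test_draws, cfg$seed)@p
      }
      write.csv(data.frame(model = nm, um, check.names = FALSE),
                file.path(cfg$outdir, sprintf("utest_%s.csv", ct)),
                row.names = FALSE)
    })
  }
  write.csv(do.call(rbind, cvRows), file.path(cfg$outdir, "cv_metrics.csv"),
            row.names = FALSE)

  if (!is.null(cfg$gene_bed)) {
    stage("genewise", {
      genes <- readBed(cfg$gene_bed)
      lab <- contrastLabels(dat$clinical, cfg$contrasts[1])
      keep <- !is.na(lab)
      m <- mapSegmentsToGenes(
        filt[mcols(filt)$sample %in% dat$clinical$sample[keep]], genes)
      m <- m[, dat$clinical$sample[keep], drop = FALSE]
      gf <- geneFisher(m, lab[keep], genes)
      write.csv(gf, file.path(cfg$outdir, "gene_fisher.csv"),
                row.names = FALSE)
      write.csv(cnvFrequency(filt, genes),
                file.path(cfg$outdir, "cnv_frequency.csv"), row.names = FALSE)
      if (!is.null(cfg$gene_sets)) {
        adj <- setNames(gf$adjusted_p, gf$gene)
        write.csv(pathwayKS(adj, readGmt(cfg$gene_sets)),
                  file.path(cfg$outdir, "pathway_ks.csv"), row.names = FALSE)
      }
    })
  }
  writeLines(.manifest(cfg), file.path(cfg$outdir, "manifest.txt"))
  logLine("done")
  invisible(cfg$outdir)
}
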