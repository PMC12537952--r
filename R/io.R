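.schemas <- list(
  trials = list(
    cols = c(animal_id = "character", genotype = "character",
             condition = "character", test = "character",
             trial = "integer", latency_s = "numeric"),
    optional = c("genotype", "condition", "test", "trial")
  ),
  enzymes = list(
    cols = c(sample_id = "character", plate_id = "character",
             assay = "character", rep1 = "numeric", rep2 = "numeric",
             nonspecific = "numeric", is_reference = "logical"),
    optional = character(0)
  ),
  qpcr = list(
    cols = c(sample_id = "character", amplicon = "character",
             ct1 = "numeric", ct2 = "numeric", ct3 = "numeric"),
    optional = "ct3"
  ),
  ocr = list(
    cols = c(well_id = "character", mouse_id = "character",
             substrate = "character", cycle = "integer",
             phase = "character", ocr = "numeric", protein_ug = "numeric"),
    optional = character(0)
  )
)

.row_err <- function(rows, rule) {
  stop(sprintf("row(s) %s: %s",
               paste(utils::head(rows, 5), collapse = ", "), rule))
}

#' Read and validate a pipeline input table
#'
#' CSV dialect is fixed (UTF-8, comma separator, dot decimal, header
#' required); the header is matched by name, order-insensitive. Value
#' rules are checked per schema -- latencies in (0, 60], Ct in (0, 45),
#' known assay/phase/amplicon labels -- and violations are reported with
#' row numbers.
#'
#' @param path CSV file path.
#' @param schema one of "trials", "enzymes", "qpcr", "ocr".
#' @param censor_point latency ceiling for the trials schema.
#' @return typed, validated data.frame.
#' @export
read_table <- function(path, schema = c("trials", "enzymes", "qpcr", "ocr"),
                       censor_point = 60) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  sc <- .schemas[[schema]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  required <- setdiff(names(sc$cols), sc$optional)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  }
  for (col in intersect(names(sc$cols), names(df))) {
    df[[col]] <- switch(sc$cols[[col]],
      character = as.character(df[[col]]),
      integer = {
        v <- suppressWarnings(as.integer(df[[col]]))
        if (any(is.na(v) & !is.na(df[[col]]))) {
          .row_err(which(is.na(v) & !is.na(df[[col]])),
                   paste0("column '", col, "' not integer"))
        }
        v
      },
      numeric = {
        v <- suppressWarnings(as.numeric(df[[col]]))
        if (any(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")) {
          .row_err(which(is.na(v) & !is.na(df[[col]]) & df[[col]] != ""),
                   paste0("column '", col, "' not numeric"))
        }
        v
      },
      logical = as.logical(df[[col]])
    )
  }
  switch(schema,
    trials = {
      bad <- which(!is.finite(df$latency_s) | df$latency_s <= 0 |
                   df$latency_s > censor_point)
      if (length(bad) > 0) {
        .row_err(bad, sprintf("latency_s must lie in (0, %g]", censor_point))
      }
      df <- validate_trials(df, censor_point)
    },
    enzymes = {
      bad <- which(!df$assay %in% c("CI", "CII", "CIV", "CS"))
      if (length(bad) > 0) .row_err(bad, "assay must be CI/CII/CIV/CS")
    },
    qpcr = {
      bad <- which(!df$amplicon %in% c("mt", "n"))
      if (length(bad) > 0) .row_err(bad, "amplicon must be 'mt' or 'n'")
      for (col in intersect(c("ct1", "ct2", "ct3"), names(df))) {
        bad <- which(!is.na(df[[col]]) &
                     (df[[col]] <= 0 | df[[col]] >= 45))
        if (length(bad) > 0) {
          .row_err(bad, paste0(col, " must lie in (0, 45)"))
        }
      }
    },
    ocr = {
      bad <- which(!df$phase %in% .ocr_phases)
      if (length(bad) > 0) {
        .row_err(bad, "phase must be substrate/adp/oligomycin/fccp/rot_aa")
      }
      bad <- which(!is.finite(df$protein_ug) | df$protein_ug <= 0)
      if (length(bad) > 0) .row_err(bad, "protein_ug must be > 0")
    }
  )
  df
}

#' Write a table in the pipeline CSV dialect
#'
#' UTF-8, comma-separated, dot decimal, newline-terminated, with header;
#' numeric values keep full precision so identical inputs give
#' byte-identical files.
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   eol = "\n", quote = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the command, input files with md5 hashes, seeds and parameters,
#' package version, skipped stages and a timestamp, so every output
#' directory documents exactly how it was produced.
#'
#' @param path output path for the manifest.
#' @param command label of the pipeline or stage.
#' @param inputs named character vector of input file paths (hashed).
#' @param params list of parameters to echo.
#' @param skipped character vector naming skipped stages.
#' @export
write_manifest <- function(path, command, inputs = character(0),
                           params = list(), skipped = character(0)) {
  hashes <- if (length(inputs) > 0) {
    as.list(tools::md5sum(unname(unlist(inputs))))
  } else list()
  manifest <- list(
    command = command,
    inputs = hashes,
    parameters = params,
    skipped_stages = as.list(skipped),
    software = list(package = "mitomotor",
                    version = as.character(utils::packageVersion("mitomotor")),
                    r_version = R.version.string),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Chains every stage over simulated or supplied inputs: synthetic-data
#' generation (optional), per-animal median latencies, per-group mixture
#' fits with parametric-bootstrap intervals, Kruskal-Wallis plus post-hoc
#' rank tests on the medians, mitochondrial feature table with MHI/MRC,
#' respirometry states with RCR, and 2x2 factorial contrasts on the
#' bioenergetic endpoints. All outputs land in `out_dir` together with a
#' JSON manifest; stages whose inputs are absent are skipped and recorded.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; drives the simulators and the bootstrap.
#' @param config a [sim_config()]; used when `inputs` is NULL.
#' @param inputs optional named list of CSV paths (`trials`, `enzymes`,
#'   `qpcr`, `ocr`); NULL simulates everything from `config`.
#' @param n_bootstrap bootstrap replicates per group fit (study scale is
#'   10,000; the default keeps exploratory runs quick).
#' @param level confidence level for bootstrap intervals.
#' @param posthoc "conover" (default, motor endpoints) or "dunn".
#' @param contrast_pairs cell contrasts for the factorial stage.
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(out_dir, seed = 1, config = sim_config(seed),
                         inputs = NULL, n_bootstrap = 1000, level = 0.95,
                         posthoc = c("conover", "dunn"),
                         contrast_pairs = c("ASO.SPF-WT.SPF",
                                            "ASO.GF-WT.GF",
                                            "ASO.SPF-ASO.GF",
                                            "WT.SPF-WT.GF")) {
  posthoc <- match.arg(posthoc)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  skipped <- character(0)
  written <- character(0)

  if (is.null(inputs)) {
    mm_log("simulate", sprintf("generating synthetic inputs (seed %d)", seed))
    sim <- simulate_all(config)
    inputs <- list()
    for (nm in names(sim)) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      write_table(sim[[nm]], p)
      inputs[[nm]] <- p
    }
  }
  get_in <- function(nm, schema) {
    if (is.null(inputs[[nm]]) || !file.exists(inputs[[nm]])) return(NULL)
    read_table(inputs[[nm]], schema)
  }

  trials <- get_in("trials", "trials")
  if (!is.null(trials)) {
    mm_log("behavior", "median summaries and per-group mixture fits")
    med <- median_summary(trials)
    write_table(med, file.path(out_dir, "medians.csv"))
    fits <- list()
    for (test in unique(trials$test)) {
      tt <- trials[trials$test == test, ]
      grp <- interaction(tt$genotype, tt$condition, drop = TRUE, sep = ".")
      for (g in levels(grp)) {
        dat <- tt[grp == g, ]
        fit <- tryCatch(fit_mle(dat), error = function(e) NULL)
        if (is.null(fit)) next
        if (fit$boundary == "omega_at_0_degenerate" || !fit$converged) {
          fits[[length(fits) + 1]] <- data.frame(
            test = test, group = g, parameter = c("omega", "mu", "sigma"),
            estimate = c(fit$params$omega, fit$params$mu, fit$params$sigma),
            lower = NA_real_, upper = NA_real_, n = fit$n_obs,
            n_censored = fit$n_censored, converged = fit$converged,
            boundary = fit$boundary, stringsAsFactors = FALSE
          )
          next
        }
        ci <- parametric_bootstrap(fit, n_replicates = n_bootstrap,
                                   level = level,
                                   seed = seed_stream(seed, 100 + length(fits)))
        fits[[length(fits) + 1]] <- data.frame(
          test = test, group = g, parameter = ci$parameter,
          estimate = ci$estimate, lower = ci$lower, upper = ci$upper,
          n = fit$n_obs, n_censored = fit$n_censored,
          converged = fit$converged, boundary = fit$boundary,
          stringsAsFactors = FALSE
        )
      }
    }
    write_table(do.call(rbind, fits), file.path(out_dir, "latency_fits.csv"))

    mm_log("rank", sprintf("Kruskal-Wallis + %s post-hoc on medians", posthoc))
    rank_rows <- list()
    for (test in unique(med$test)) {
      m <- med[med$test == test, ]
      grp <- paste(m$genotype, m$condition, sep = ".")
      kw <- kruskal_wallis(m$median_latency_s, grp)
      ph <- if (posthoc == "conover") {
        conover_posthoc(m$median_latency_s, grp, kw)
      } else {
        dunn_posthoc(m$median_latency_s, grp)
      }
      ph$test <- test
      ph$kw_H <- kw$H
      ph$kw_p <- kw$p
      rank_rows[[length(rank_rows) + 1]] <- ph
    }
    write_table(do.call(rbind, rank_rows),
                file.path(out_dir, "rank_tests.csv"))
  } else {
    skipped <- c(skipped, "behavior", "rank")
  }

  enzymes <- get_in("enzymes", "enzymes")
  qpcr <- get_in("qpcr", "qpcr")
  feat <- NULL
  if (!is.null(enzymes) && !is.null(qpcr)) {
    mm_log("bioenergetics", "mitochondrial feature table (MHI/MRC)")
    feat <- mito_features(enzymes, qpcr)
    out_feat <- feat
    out_feat$mrc_cohort <- attr(feat, "mrc_cohort")
    write_table(out_feat, file.path(out_dir, "mito_features.csv"))
  } else {
    skipped <- c(skipped, "bioenergetics")
    if (is.null(qpcr)) {
      mm_log("bioenergetics", "qPCR input absent; mtDNA outputs skipped",
             "warning")
    }
  }

  ocr <- get_in("ocr", "ocr")
  states <- NULL
  if (!is.null(ocr)) {
    mm_log("respirometry", "respiration states and RCR")
    states <- ocr_states(ocr)
    write_table(states, file.path(out_dir, "states.csv"))
  } else {
    skipped <- c(skipped, "respirometry")
  }

  if (!is.null(trials) && (!is.null(feat) || !is.null(states))) {
    mm_log("factorial", "2x2 genotype x condition contrasts")
    labels <- unique(trials[c("animal_id", "genotype", "condition")])
    rows <- list()
    add_endpoint <- function(ids, values, endpoint) {
      i <- match(ids, labels$animal_id)
      ok <- !is.na(i) & is.finite(values)
      if (sum(ok) < 8) return()
      ffit <- tryCatch(
        fit_two_factor(values[ok], labels$genotype[i[ok]],
                       labels$condition[i[ok]]),
        error = function(e) NULL
      )
      if (is.null(ffit)) return()
      ct <- pairwise_contrasts(ffit, contrast_pairs)
      ct$endpoint <- endpoint
      rows[[length(rows) + 1]] <<- ct
    }
    if (!is.null(feat)) {
      add_endpoint(feat$sample_id, feat$mhi, "mhi")
      add_endpoint(feat$sample_id, feat$mtdnacn, "mtdnacn")
    }
    if (!is.null(states)) {
      for (sub in unique(states$substrate)) {
        s <- states[states$substrate == sub, ]
        add_endpoint(s$mouse_id, s$state3u, paste0("state3u_", sub))
        add_endpoint(s$mouse_id, s$rcr, paste0("rcr_", sub))
      }
    }
    if (length(rows) > 0) {
      write_table(do.call(rbind, rows),
                  file.path(out_dir, "factorial_contrasts.csv"))
    }
  } else {
    skipped <- c(skipped, "factorial")
  }

  write_manifest(
    file.path(out_dir, "manifest.json"), command = "run_pipeline",
    inputs = unlist(inputs[!vapply(inputs, is.null, logical(1))]),
    params = list(seed = seed, n_bootstrap = n_bootstrap, level = level,
                  posthoc = posthoc, contrast_pairs = contrast_pairs),
    skipped = unique(skipped)
  )
  invisible(out_dir)
}
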