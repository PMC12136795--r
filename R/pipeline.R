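#' Read and write intensity-trace tables
#'
#' Traces are stored as CSV with columns \code{molecule_id}, \code{frame},
#' \code{time_s}, \code{intensity} and optionally \code{truth_state};
#' unknown extra columns are preserved verbatim so round trips are
#' lossless.
#'
#' @param path CSV file.
#' @return data.frame of traces.
#' @export
readTraces <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "frame", "time_s", "intensity")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("trace table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in c("frame", "time_s", "intensity")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(sprintf("malformed value in column '%s' at line %d", col,
                   bad[1L] + 1L))
    }
    df[[col]] <- v
  }
  df
}

#' @rdname readTraces
#' @param traces data.frame of traces.
#' @export
writeTraces <- function(traces, path) {
  write.csv(traces, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a DwellSet as CSV
#'
#' @param dwells a \linkS4class{DwellSet}.
#' @param path CSV file.
#' @export
writeDwells <- function(dwells, path) {
  write.csv(dwells@dwells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDwells
#' @export
readDwells <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$censored <- as.logical(df$censored)
  new("DwellSet", dwells = df)
}

#' Read a pipeline run configuration
#'
#' Configurations are YAML with the documented keys (\code{seed},
#' \code{outDir}, \code{stages}, \code{scheme}, \code{simulate},
#' \code{idealize}, \code{dwells}, \code{fitrates}, \code{fp}); a list with
#' the same structure is accepted directly by \code{\link{runPipeline}}.
#'
#' @param path YAML file.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

validateConfig <- function(config) {
  if (is.null(config$seed)) stop("config must set an explicit seed")
  config$stages <- config$stages %||% character(0)
  known <- c("simulate", "idealize", "dwells", "fitmix", "fitrates", "fp")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.null(config$tracePath) && !file.exists(config$tracePath)) {
    stop("input trace path does not exist: ", config$tracePath)
  }
  if (("idealize" %in% config$stages) &&
      !("simulate" %in% config$stages) && is.null(config$tracePath)) {
    stop("idealize stage needs simulated traces or a tracePath input")
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

configScheme <- function(config) {
  sc <- config$scheme %||% list()
  kon <- sc$kon %||% 1.94e7
  koff <- sc$koff %||% 0.045
  rare <- sc$rare %||% 0.002
  switch(sc$type %||% "fourState",
         twoState = twoStateScheme(kon, koff),
         fourState = fourStateScheme(kon, koff, rare, rare, rare, rare),
         stop("unknown scheme type: ", sc$type))
}

#' Run the CoSMoS analysis pipeline
#'
#' Executes the enabled stages in dependency order: \code{simulate}
#' (synthetic traces at each configured concentration), \code{idealize}
#' (DISC), \code{dwells} (binary dwell extraction), \code{fitmix}
#' (exponential-mixture dwell fits), \code{fitrates} (global kinetic-scheme
#' fitting with BIC selection) and \code{fp} (four-parameter logistic
#' titration fit). Outputs are written to \code{config$outDir} when set,
#' together with a provenance record (config, package version); re-running
#' with the identical config reproduces identical files. A stage failure
#' marks the bundle partial and skips downstream stages.
#'
#' @param config list (see \code{\link{readRunConfig}}) or YAML path.
#' @return the report bundle: list with per-stage outputs, \code{counts},
#'   \code{partial} flag and \code{provenance}.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- validateConfig(config)
  outDir <- config$outDir
  if (!is.null(outDir) && !dir.exists(outDir)) {
    dir.create(outDir, recursive = TRUE)
  }
  bundle <- list(counts = list(), partial = FALSE,
                 provenance = list(
                   config = config,
                   package = as.character(utils::packageVersion(
                     "cosmosKinetics"))))
  stages <- config$stages
  log <- function(...) message("[cosmosKinetics] ", sprintf(...))
  fail <- function(stage, e) {
    warning(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    bundle$partial <<- TRUE
  }
  frameInterval <- config$simulate$frameInterval %||% 3

  if ("simulate" %in% stages) {
    tryCatch({
      sim <- config$simulate %||% list()
      concs <- sim$concentrations %||% 10
      scheme <- configScheme(config)
      seeds <- subSeeds(config$seed, length(concs))
      bundle$traces <- lapply(seq_along(concs), function(i) {
        cfg <- simConfig(seed = seeds[i],
                         frameInterval = frameInterval,
                         movieLength = sim$movieLength %||% 1800,
                         nMolecules = sim$nMolecules %||% 50L,
                         concentration = concs[i])
        simulateTraces(scheme, cfg)
      })
      names(bundle$traces) <- as.character(concs)
      bundle$scheme <- scheme
      bundle$counts$traces <- sum(vapply(bundle$traces, function(tr)
        length(unique(tr$molecule_id)), 0))
      log("simulate: %d traces at %d concentration(s)",
          bundle$counts$traces, length(concs))
      if (!is.null(outDir)) {
        for (cn in names(bundle$traces)) {
          writeTraces(bundle$traces[[cn]],
                      file.path(outDir, sprintf("traces_%snM.csv", cn)))
        }
      }
    }, error = function(e) fail("simulate", e))
  } else if (!is.null(config$tracePath)) {
    tr <- readTraces(config$tracePath)
    bundle$traces <- list(`0` = tr)
    names(bundle$traces) <- as.character(config$concentration %||% 0)
  }

  if ("idealize" %in% stages && !bundle$partial &&
      !is.null(bundle$traces)) {
    tryCatch({
      maxStates <- config$idealize$maxStates %||% 4L
      bundle$ideals <- lapply(bundle$traces, function(tr) {
        lapply(split(tr$intensity, tr$molecule_id), idealizeDISC,
               maxStates = maxStates, frameInterval = frameInterval)
      })
      bundle$counts$ideals <- sum(lengths(bundle$ideals))
      log("idealize: %d traces idealized", bundle$counts$ideals)
    }, error = function(e) fail("idealize", e))
  }

  if ("dwells" %in% stages && !bundle$partial && !is.null(bundle$ideals)) {
    tryCatch({
      bundle$dwells <- lapply(bundle$ideals, function(ids) {
        extractDwells(lapply(ids, toBinary), frameInterval)
      })
      bundle$counts$dwells <- sum(vapply(bundle$dwells, function(d)
        nrow(d@dwells), 0))
      log("dwells: %d dwells extracted", bundle$counts$dwells)
      if (!is.null(outDir)) {
        for (cn in names(bundle$dwells)) {
          writeDwells(bundle$dwells[[cn]],
                      file.path(outDir, sprintf("dwells_%snM.csv", cn)))
        }
      }
    }, error = function(e) fail("dwells", e))
  }

  if ("fitmix" %in% stages && !bundle$partial && !is.null(bundle$dwells)) {
    tryCatch({
      cen <- config$dwells$censoring %||% "drop"
      bundle$mixtureFits <- lapply(bundle$dwells, function(d) {
        lapply(c(bound = "bound", unbound = "unbound"), function(st) {
          tryCatch(selectMixtureModel(d, Kmax = 2L, seed = config$seed,
                                      censoring = cen, state = st),
                   error = function(e) NULL)
        })
      })
      log("fitmix: mixture models fitted")
      if (!is.null(outDir)) {
        rep <- lapply(bundle$mixtureFits, function(byState) {
          lapply(byState, function(mc) {
            if (is.null(mc)) return(NULL)
            sel <- mc@fits[[mc@selectedK]]
            list(K = sel@K, A = sel@A, tau = sel@tau, logL = sel@logL,
                 selected = mc@selected)
          })
        })
        jsonlite::write_json(rep, file.path(outDir, "mixture_fits.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }, error = function(e) fail("fitmix", e))
  }

  if ("fitrates" %in% stages && !bundle$partial &&
      !is.null(bundle$ideals)) {
    tryCatch({
      datasets <- lapply(names(bundle$ideals), function(cn) {
        list(concentration = as.numeric(cn),
             classes = lapply(bundle$ideals[[cn]], toClassSeries))
      })
      cand <- list(twoStateScheme(), threeStateBoundScheme(),
                   fourStateScheme())
      sel <- selectScheme(cand, datasets, frameInterval,
                          seed = config$seed)
      bundle$kinetics <- sel
      best <- sel$results[[1L]]
      log("fitrates: best scheme has %d free parameters, BIC %.1f",
          length(best@rates), best@bic)
      if (!is.null(outDir)) {
        jsonlite::write_json(
          list(rates = as.list(best@rates), logL = best@logL,
               bic = best@bic, nFrames = best@nFrames,
               table = sel$table),
          file.path(outDir, "kinetics.json"), auto_unbox = TRUE,
          digits = NA)
      }
    }, error = function(e) fail("fitrates", e))
  }

  if ("fp" %in% stages && !bundle$partial) {
    tryCatch({
      fp <- config$fp %||% list()
      params <- fourPLParams(FPmin = fp$FPmin %||% 0,
                             FPmax = fp$FPmax %||% 100,
                             KD = fp$KD %||% 10, H = fp$H %||% 1)
      concs <- fp$concentrations %||% 10^seq(-2, 3, length.out = 12)
      dat <- generateFPDataset(params, concs, noiseSD = fp$noiseSD %||% 2,
                               seed = config$seed)
      bundle$fpFit <- fit4PL(dat, seed = config$seed)
      log("fp: KD = %.3g nM", bundle$fpFit@KD)
    }, error = function(e) fail("fp", e))
  }

  if (!is.null(outDir)) {
    jsonlite::write_json(bundle$provenance,
                         file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  bundle
}
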