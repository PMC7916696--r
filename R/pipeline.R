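#' Read and validate a pipeline run configuration
#'
#' A YAML document with either an \code{input:} CSV path or a
#' \code{synthetic:} design block (see [syntheticSpecToYAML()]), plus
#' optional processing settings.  Missing settings take the package
#' defaults:
#' \preformatted{
#' input: spectra.csv          # or synthetic: {bands: [...], ...}
#' region: [900, 1200]         # cm^-1; omit to use the full grid
#' reference: first            # first | last | mean | zero | integer index
#' baseline: linear_endpoints  # linear_endpoints | none
#' normalization:
#'   mode: band_area           # band_area | vector | none
#'   window: [1045, 1065]      # internal-standard window (cm^-1)
#' peaks:
#'   threshold_frac: 0.05
#'   sign_epsilon: 0.05
#'   min_separation: 8         # cm^-1
#' slices: [992, 1021, 1049]   # nu2 values for asynchronous slices
#' output: out/                # output directory
#' seed: 1
#' }
#'
#' @param x path to a YAML file, a YAML string, or an already-parsed list.
#' @return a validated configuration list (class \code{RunConfig}).
#' @export
readRunConfig <- function(x) {
  cfg <- if (is.list(x)) x
         else if (length(x) == 1L && file.exists(x)) yaml::read_yaml(x)
         else yaml::yaml.load(x)
  if (is.null(cfg$input) && is.null(cfg$synthetic)) {
    stop("config must provide either 'input' (CSV path) or a 'synthetic' block")
  }
  cfg$reference <- cfg$reference %||% "first"
  cfg$baseline <- cfg$baseline %||% "linear_endpoints"
  nrm <- cfg$normalization %||% list()
  cfg$normalization <- list(
    mode = nrm$mode %||% "band_area",
    window = as.numeric(nrm$window %||% c(1045, 1065))
  )
  pk <- cfg$peaks %||% list()
  ms <- pk$min_separation
  if (!length(ms) || !is.numeric(unlist(ms))) ms <- NULL
  cfg$peaks <- list(
    threshold_frac = pk$threshold_frac %||% 0.05,
    sign_epsilon = pk$sign_epsilon %||% 0.05,
    min_separation = if (is.null(ms)) NULL else as.numeric(unlist(ms))
  )
  cfg$slices <- as.numeric(cfg$slices %||% numeric())
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (!is.null(cfg$region)) {
    cfg$region <- as.numeric(cfg$region)
    if (length(cfg$region) != 2L || cfg$region[1] >= cfg$region[2]) {
      stop("region must be two increasing wavenumbers")
    }
  }
  for (nm in c("threshold_frac", "sign_epsilon")) {
    v <- cfg$peaks[[nm]]
    if (!(v > 0 && v < 1)) stop(nm, " must be in (0, 1)")
  }
  structure(cfg, class = c("RunConfig", "list"))
}

#' Run the full 2D correlation pipeline
#'
#' Executes, in order: load (or simulate) the series, restrict to the
#' analysis region, baseline-correct, normalize, resample to an even
#' temperature grid if needed, compute both correlation maps, detect auto-
#' and cross-peaks, infer the sequential order, extract the requested
#' asynchronous slices, and write every artifact into the output directory:
#' \code{series.csv}, \code{sync.csv}, \code{async.csv},
#' \code{autopeaks.csv}, \code{crosspeaks.csv}, \code{order.csv},
#' \code{order.txt}, \code{slice_<nu2>.csv}, \code{sync_map.png},
#' \code{async_map.png}, and a machine-readable \code{run_log.json}
#' recording every resolved parameter and the package version (sufficient to
#' replay the run, see [replayRun()]).  Identical configuration and seed
#' give byte-identical CSV outputs.  Any stage failure aborts with the stage
#' name.
#'
#' @param config a configuration accepted by [readRunConfig()].
#' @param outputDir overrides the configured output directory.
#' @return invisibly, a list with the computed objects (\code{series},
#'   \code{maps}, \code{autopeaks}, \code{crosspeaks}, \code{order},
#'   \code{slices}, \code{truth} when synthetic) and \code{files}.
#' @examples
#' \dontrun{
#' res <- runPipeline(demoConfig("cns-low"), outputDir = tempfile())
#' res$order
#' }
#' @export
runPipeline <- function(config, outputDir = NULL) {
  cfg <- readRunConfig(config)
  out <- outputDir %||% cfg$output %||% stop("no output directory configured")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  truth <- NULL
  series <- stage("load", {
    if (!is.null(cfg$input)) {
      readSeries(cfg$input)
    } else {
      sp <- syntheticSpecFromList(cfg$synthetic)
      if (is.null(cfg$synthetic$seed)) sp@seed <- cfg$seed
      sim <- generateSeries(sp)
      truth <- sim$truth
      sim$series
    }
  })
  if (!is.null(cfg$region)) {
    series <- stage("select_region",
                    selectRegion(series, cfg$region[1], cfg$region[2]))
  }
  series <- stage("baseline", baselineCorrect(series, cfg$baseline))
  series <- stage("normalize",
                  normalizeSeries(series, cfg$normalization$mode,
                                  cfg$normalization$window))
  series <- stage("resample", {
    if (nSpectra(series) >= 3L) resampleEven(series) else series
  })

  maps <- stage("correlate", correlate2d(series, cfg$reference))
  aps <- stage("autopeaks", detectAutopeaks(maps, cfg$peaks$threshold_frac))
  cps <- stage("crosspeaks", detectCrosspeaks(
    maps, cfg$peaks$threshold_frac,
    minSeparation = cfg$peaks$min_separation,
    signEpsilon = cfg$peaks$sign_epsilon
  ))
  ord <- stage("order", applyNodaRules(cps))
  slices <- stage("slices", lapply(cfg$slices, function(s) sliceAsync(maps, s)))

  files <- stage("write", {
    f <- c(
      series = file.path(out, "series.csv"),
      sync = file.path(out, "sync.csv"),
      async = file.path(out, "async.csv"),
      autopeaks = file.path(out, "autopeaks.csv"),
      crosspeaks = file.path(out, "crosspeaks.csv"),
      order_csv = file.path(out, "order.csv"),
      order_txt = file.path(out, "order.txt"),
      log = file.path(out, "run_log.json")
    )
    writeSeries(series, f[["series"]])
    writeMaps(maps, f[["sync"]], f[["async"]])
    writePeakTable(aps, f[["autopeaks"]])
    writePeakTable(cps, f[["crosspeaks"]])
    writeOrderReport(ord, f[["order_csv"]], f[["order_txt"]])
    for (sl in slices) {
      p <- file.path(out, sprintf("slice_%g.csv", attr(sl, "nu2")))
      writeSlice(sl, p)
      f <- c(f, p)
    }
    f
  })

  figs <- stage("figures", {
    fs <- file.path(out, "sync_map.png")
    fa <- file.path(out, "async_map.png")
    grDevices::png(fs, width = 900, height = 800)
    plotCorrelationMap(maps, "sync")
    grDevices::dev.off()
    grDevices::png(fa, width = 900, height = 800)
    plotCorrelationMap(maps, "async")
    grDevices::dev.off()
    c(fs, fa)
  })

  stage("log", {
    log <- list(
      package = "noda2d",
      version = as.character(utils::packageVersion("noda2d")),
      timestamp = format(Sys.time(), tz = "UTC"),
      config = unclass(cfg)
    )
    jsonlite::write_json(log, files[["log"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  })

  invisible(list(
    series = series, maps = maps, autopeaks = aps, crosspeaks = cps,
    order = ord, slices = slices, truth = truth,
    files = c(files, figures = figs)
  ))
}

#' Replay a pipeline run from its machine-readable log
#'
#' Reads \code{run_log.json} written by [runPipeline()] and re-executes the
#' run with the recorded configuration.
#'
#' @param logPath path to a \code{run_log.json}.
#' @param outputDir where to write the replayed artifacts.
#' @return see [runPipeline()].
#' @export
replayRun <- function(logPath, outputDir) {
  log <- jsonlite::read_json(logPath, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  runPipeline(log$config, outputDir = outputDir)
}

#' Contour plot of a correlation map
#'
#' Filled image of the synchronous or asynchronous map with a diverging
#' palette (blue = negative, white = zero, red = positive), contour lines,
#' and the diagonal drawn.
#'
#' @param maps a [CorrelationMaps-class].
#' @param which \code{"sync"} or \code{"async"}.
#' @param nLevels number of contour levels (default 12).
#' @param main plot title; a default naming the map is used when omitted.
#' @return invisibly, \code{NULL}.
#' @export
plotCorrelationMap <- function(maps, which = c("sync", "async"),
                               nLevels = 12, main = NULL) {
  stopifnot(is(maps, "CorrelationMaps"))
  which <- match.arg(which)
  m <- if (which == "sync") maps@sync else maps@async
  nu <- maps@wavenumber
  lim <- max(abs(m), 1e-300)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(64)
  graphics::image(nu, nu, t(m), zlim = c(-lim, lim), col = pal,
                  xlab = expression(nu[1] ~ (cm^-1)),
                  ylab = expression(nu[2] ~ (cm^-1)),
                  main = main %||% sprintf("%s 2D correlation map",
                    if (which == "sync") "Synchronous" else "Asynchronous"),
                  useRaster = TRUE)
  graphics::contour(nu, nu, t(m), nlevels = nLevels, add = TRUE,
                    drawlabels = FALSE, col = "grey30")
  graphics::abline(0, 1, lty = 2)
  invisible(NULL)
}

#' Packaged demonstration configurations
#'
#' Three ready-made synthetic configurations emulating the three
#' mid-infrared analysis windows of a cellulose nano-sponge study:
#' \code{"cns-low"} (900--1200 cm^-1 fingerprint region, bands at
#' 992/1021/1031/1055/1108/1161 cm^-1 with staggered response onsets),
#' \code{"cns-amide"} (1500--1700 cm^-1 carbonyl/amide region) and
#' \code{"cns-hydroxyl"} (2680--3780 cm^-1 hydrogen-bond stretching region).
#' Their purpose is documentation of the workflow on look-alike data, not
#' numerical reproduction of any measured dataset.
#'
#' @param name one of \code{"cns-low"}, \code{"cns-amide"},
#'   \code{"cns-hydroxyl"}.
#' @return the parsed configuration list (pass to [runPipeline()]).
#' @export
demoConfig <- function(name = c("cns-low", "cns-amide", "cns-hydroxyl")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "noda2d",
                      mustWork = TRUE)
  readRunConfig(path)
}
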