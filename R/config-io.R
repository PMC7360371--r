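#' @include AllClasses.R observables.R
NULL

.CONFIG_KEYS <- c("latticeSize", "nParticles", "phiLattice", "valency",
                  "epsSp", "epsNs", "kDiff", "kBond", "tEnd", "seed",
                  "snapshotInterval", "rateConvention",
                  "replicates", "sweep", "outDir", "logLevel")

#' Load and save run configurations
#'
#' Configurations are human-editable YAML whose keys mirror the
#' [SimParams-class] field names exactly (`latticeSize`, `phiLattice` *or*
#' `nParticles`, `valency`, `epsSp`, `epsNs`, `kDiff`, `kBond`, `tEnd`,
#' `seed`, `snapshotInterval`, `rateConvention`) plus run plumbing
#' (`replicates`, `sweep`, `outDir`, `logLevel`).  Unknown keys are
#' rejected by name.  Defaults fill in the standard study conditions:
#' `kDiff = 1` /s, `epsNs = 0.35` kT, `tEnd = 7200` s.
#'
#' @param path YAML file path.
#' @return `loadConfig()`: a list with class `"RunConfig"` containing a
#'   resolved `params` ([SimParams-class]) plus `replicates`, `sweep`,
#'   `outDir`, `logLevel`.  `saveConfig()` writes YAML that round-trips
#'   through `loadConfig()` and returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines(c("latticeSize: 50", "phiLattice: 0.04",
#'              "valency: 5", "epsSp: 3.0"), f)
#' cfg <- loadConfig(f)
#' kDiff(cfg$params)  # default 1
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$phiLattice)) {
    if (!is.null(raw$nParticles))
      stop("config error in key 'phiLattice': give phiLattice or nParticles, not both")
    if (raw$phiLattice <= 0 || raw$phiLattice > 1)
      stop("config error in key 'phiLattice': must lie in (0, 1]")
  }
  get <- function(key, default) if (is.null(raw[[key]])) default else raw[[key]]
  tEnd <- get("tEnd", 7200)
  params <- tryCatch(
    SimParams(
      latticeSize = get("latticeSize", 100L),
      nParticles = raw$nParticles,
      phi = raw$phiLattice,
      valency = get("valency", 5L),
      epsSp = get("epsSp", 3),
      epsNs = get("epsNs", 0.35),
      kDiff = get("kDiff", 1),
      kBond = get("kBond", 1),
      tEnd = tEnd,
      seed = get("seed", 1L),
      snapshotInterval = get("snapshotInterval", tEnd / 20),
      rateConvention = get("rateConvention", "per_direction")),
    error = function(e) stop("config error: ", conditionMessage(e)))
  validObject(params)
  structure(list(params = params,
                 replicates = as.integer(get("replicates", 1L)),
                 sweep = raw$sweep,
                 outDir = get("outDir", "."),
                 logLevel = get("logLevel", "info")),
            class = "RunConfig")
}

#' @rdname loadConfig
#' @param config a `RunConfig` (from [loadConfig()]).
#' @export
saveConfig <- function(config, path) {
  p <- config$params
  out <- list(latticeSize = latticeSize(p), nParticles = nParticles(p),
              valency = valency(p), epsSp = epsSp(p), epsNs = epsNs(p),
              kDiff = kDiff(p), kBond = kBond(p), tEnd = tEnd(p),
              seed = simSeed(p), snapshotInterval = p@snapshotInterval,
              rateConvention = p@rateConvention,
              replicates = config$replicates, outDir = config$outDir,
              logLevel = config$logLevel)
  if (!is.null(config$sweep)) out$sweep <- config$sweep
  yaml::write_yaml(out, path)
  invisible(path)
}

.configHash <- function(params) {
  # small content hash so outputs embed which configuration produced them
  s <- paste(latticeSize(params), nParticles(params), valency(params),
             epsSp(params), epsNs(params), kDiff(params), kBond(params),
             tEnd(params), params@snapshotInterval, params@rateConvention,
             sep = "|")
  v <- utils::head(utf8ToInt(s), 1000)
  sprintf("%08x", as.integer(sum(v * (31^(seq_along(v) %% 8))) %% 2147483647))
}

#' Write a JSON run summary
#'
#' Every scientific output embeds the fully resolved configuration, the
#' seed list, a config hash and the package version, so results can be
#' traced to the run that produced them; nothing depends on wall-clock or
#' hardware.
#'
#' @param results named list of results (must be JSON-representable).
#' @param path output file.
#' @param params the [SimParams-class] used.
#' @param seeds integer vector of seeds used.
#' @return `path`, invisibly.
#' @export
writeSummary <- function(results, path, params, seeds = simSeed(params)) {
  payload <- list(
    package = "condensateKMC",
    version = as.character(utils::packageVersion("condensateKMC")),
    configHash = .configHash(params),
    config = list(latticeSize = latticeSize(params),
                  nParticles = nParticles(params),
                  phiLattice = phiLattice(params),
                  valency = valency(params), epsSp = epsSp(params),
                  epsNs = epsNs(params), kDiff = kDiff(params),
                  kBond = kBond(params), kBreak = kBreak(params),
                  tEnd = tEnd(params),
                  snapshotInterval = params@snapshotInterval,
                  rateConvention = params@rateConvention),
    seeds = as.integer(seeds),
    results = results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a TSV results table
#'
#' Fixed column order as given, tab-separated, numeric columns at 6
#' significant digits; an empty table still emits its header line.
#'
#' @param rows a data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTable <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.FIXTURES <- c("single_particle", "adjacent_pair", "bonded_dimer",
               "block2x2", "plus5", "toy_chain")

#' Deterministic test fixtures
#'
#' Named small scenarios used throughout the test-suite and examples, each
#' reproducible byte-identically from its name (and seed, where placement
#' is random):
#' \describe{
#'   \item{single_particle}{one particle at the centre of a 9 x 9 lattice.}
#'   \item{adjacent_pair}{two horizontally adjacent particles, no bond.}
#'   \item{bonded_dimer}{the adjacent pair with one specific bond
#'     (both `usedValency` 1); pair it with `valency = 1` parameters.}
#'   \item{block2x2}{a 2 x 2 block of particles.}
#'   \item{plus5}{a centre particle with all four neighbour sites occupied
#'     (the buried state of the exchange observable).}
#'   \item{toy_chain}{a 9-bead conformation: 2 domains joined by a 7-bead
#'     linker, every backbone bond at its rest length.}
#' }
#'
#' @param name fixture name.
#' @param seed integer (reserved for randomized fixtures).
#' @return A [LatticeState-class] or [ChainConformation-class].
#' @examples
#' makeFixture("plus5")
#' @export
makeFixture <- function(name, seed = 1L) {
  if (!name %in% .FIXTURES)
    stop("unknown fixture '", name, "'; available: ",
         paste(.FIXTURES, collapse = ", "))
  L <- 9L
  switch(name,
    single_particle = .newLatticeState(L, cbind(4L, 4L)),
    adjacent_pair = .newLatticeState(L, cbind(c(4L, 4L), c(4L, 5L))),
    bonded_dimer = .newLatticeState(L, cbind(c(4L, 4L), c(4L, 5L)),
                                    bonds = cbind(1L, 2L, 1L)),
    block2x2 = .newLatticeState(L, cbind(c(4L, 4L, 5L, 5L),
                                         c(4L, 5L, 4L, 5L))),
    plus5 = .newLatticeState(L, cbind(c(4L, 3L, 5L, 4L, 4L),
                                      c(4L, 4L, 4L, 3L, 5L))),
    toy_chain = buildChain(chainTopology(nDomains = 2L, linkerLength = 7L)))
}
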