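#' Read a DDP instance from JSON or 3-line text
#'
#' Two dialects are auto-detected: a JSON object
#' \code{{"name": ..., "a": [...], "b": [...], "c": [...]}} and a plain
#' text format with the three digests whitespace-separated on three lines
#' (order a, b, c). Negative lengths are rejected; an instance whose totals
#' disagree loads with a warning (so that it can be diagnosed with
#' [validateInstance()]) rather than an error.
#'
#' @param path file path.
#' @return a [DDPInstance-class].
#' @export
readInstance <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- readLines(path, warn = FALSE)
  isJSON <- length(txt) > 0L && grepl("^\\s*\\{", paste(txt, collapse = "\n"))
  inst <- if (isJSON) .readInstanceJSON(path) else .readInstanceText(txt, path)
  rep_ <- validateInstance(inst)
  if (!rep_$valid)
    warning(sprintf("instance '%s' loaded but %s", instanceName(inst),
                    rep_$message))
  inst
}

.readInstanceJSON <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e)))
  for (fld in c("a", "b", "c"))
    if (is.null(obj[[fld]]))
      stop(sprintf("parse error in %s: missing field '%s'", path, fld))
  .checkNonNegative(obj, path)
  DDPInstance(obj$a, obj$b, obj$c,
              name = if (is.null(obj$name)) basename(path) else obj$name)
}

.readInstanceText <- function(txt, path) {
  txt <- txt[nzchar(trimws(txt))]
  if (length(txt) != 3L)
    stop(sprintf("parse error in %s: expected 3 non-empty lines, found %d",
                 path, length(txt)))
  vecs <- lapply(seq_along(txt), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(txt[i]), "\\s+")[[1L]]))
    if (anyNA(v))
      stop(sprintf("parse error in %s, line %d: non-numeric entry", path, i))
    v
  })
  .checkNonNegative(list(a = vecs[[1]], b = vecs[[2]], c = vecs[[3]]), path)
  DDPInstance(vecs[[1]], vecs[[2]], vecs[[3]],
              name = sub("\\.[^.]*$", "", basename(path)))
}

.checkNonNegative <- function(obj, path) {
  for (fld in c("a", "b", "c"))
    if (any(obj[[fld]] < 0))
      stop(sprintf("domain error in %s: negative fragment length in '%s'",
                   path, fld))
}

#' Write a DDP instance to JSON or 3-line text
#'
#' @param x a [DDPInstance-class].
#' @param path destination file.
#' @param format "json" (default) or "text".
#' @return invisibly, \code{path}.
#' @export
writeInstance <- function(x, path, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(name = x@name, a = x@a, b = x@b, c = x@c),
                         path, auto_unbox = TRUE)
  } else {
    writeLines(vapply(list(x@a, x@b, x@c), paste, character(1),
                      collapse = " "), path)
  }
  invisible(path)
}

#' Serialize a solution record to JSON
#'
#' Permutations are written 1-based in one-line notation.
#'
#' @param x a [SolutionRecord-class].
#' @param path destination file; NULL returns the JSON string.
#' @return invisibly, the path (or the JSON string when \code{path} is
#'   NULL).
#' @export
writeSolution <- function(x, path = NULL) {
  obj <- list(mu = x@mu, nu = x@nu, pi = x@pi, dds = x@dds,
              mismatch = x@mismatch, fitness = x@fitness,
              generation_found = x@generationFound)
  if (is.null(path))
    return(invisible(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' Build a run manifest for reproducibility
#'
#' Every CLI artifact embeds a manifest tying the output to the command,
#' configuration, seed, package version and a checksum of the input file.
#' Reruns with equal manifests produce equal outputs (timing aside).
#'
#' @param command character command name.
#' @param config a [GAConfig-class] or NULL.
#' @param seed integer seed.
#' @param inputPath optional instance file digested with MD5.
#' @return named list.
#' @export
runManifest <- function(command, config = NULL, seed = NA_integer_,
                        inputPath = NULL) {
  list(command = command,
       config = if (is.null(config)) NULL else list(
         population_size = config@populationSize,
         max_generations = config@maxGenerations,
         crossover_prob = config@crossoverProb,
         crossovers = config@crossovers,
         mutations = config@mutations,
         cycle_length = config@cycleLength,
         mutation_ceiling = config@mutationCeiling,
         elite_count = config@eliteCount),
       seed = seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       package_version = as.character(utils::packageVersion("digestmap")),
       input_digest = if (is.null(inputPath)) NULL else
         unname(tools::md5sum(inputPath)))
}
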