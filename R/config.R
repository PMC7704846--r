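#' @title Configuration files and run manifests
#' @name dutchpt-config
NULL

config_keys <- c("duration_s", "dt_s", "start_price_low", "start_price_high",
                 "unit_mode", "unit_low", "unit_high", "budget", "warehouse",
                 "n_groups", "n_blocks", "trials_per_block", "seed",
                 "alpha", "beta", "lambda", "gamma", "delta", "c", "V",
                 "mu", "sigma", "softmax_sign", "value_anchor",
                 "wait_exponent", "condition", "n_auctions")

# minimal flat "key: value" reader covering the documented key set;
# JSON files go through jsonlite
parse_flat_yaml <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop("cannot parse config line: '", ln, "'", call. = FALSE)
    key <- m[2]; val <- trimws(m[3])
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Read a model/auction configuration file
#'
#' Accepts JSON or a flat `key: value` YAML subset. Unknown keys raise an
#' error naming the key; all keys are optional, with defaults supplied by
#' [default_config()].
#'
#' @param path Config file path (`.json`, `.yaml` or `.yml`).
#' @return A named list of configuration values merged over the defaults.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    parse_flat_yaml(readLines(path, warn = FALSE))
  }
  bad <- setdiff(names(cfg), config_keys)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  utils::modifyList(default_config(), cfg)
}

#' Default configuration
#'
#' The model-study continuous-condition configuration: 5 s auctions,
#' dt = 0.05 s, start prices U($80, $120), classic utility/weighting
#' parameters, fitted belief (mu = 2.01, sigma = 0.97) and continuous-clock
#' fits V = 1.27, c = 2.1.
#'
#' @param condition `"continuous"` or `"discrete"`; the discrete variant
#'   switches dt to 0.5 and (V, c) to (1.43, 0.3).
#' @return Named list of config values.
#' @export
default_config <- function(condition = c("continuous", "discrete")) {
  condition <- match.arg(condition)
  cfg <- list(
    duration_s = 5, dt_s = 0.05,
    start_price_low = 80, start_price_high = 120,
    unit_mode = "fixed", unit_low = 50, unit_high = 150,
    budget = 250, warehouse = 500,
    n_groups = 11, n_blocks = 5, trials_per_block = 12,
    seed = 1,
    alpha = 0.88, beta = 0.88, lambda = 2.25, gamma = 0.61, delta = 0.69,
    c = 2.1, V = 1.27, mu = 2.01, sigma = 0.97,
    softmax_sign = "corrected", value_anchor = "start_price",
    wait_exponent = "by_sign",
    condition = condition, n_auctions = 1000
  )
  if (condition == "discrete") {
    cfg$dt_s <- 0.5; cfg$V <- 1.43; cfg$c <- 0.3
  }
  cfg
}

config_params <- function(cfg) {
  prospect_params(alpha = cfg$alpha, beta = cfg$beta, lambda = cfg$lambda,
                  gamma = cfg$gamma, delta = cfg$delta, c = cfg$c, V = cfg$V,
                  value_anchor = cfg$value_anchor,
                  softmax_sign = cfg$softmax_sign,
                  wait_exponent = cfg$wait_exponent)
}

config_belief <- function(cfg) opponent_belief(mu = cfg$mu, sigma = cfg$sigma)

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write a run manifest
#'
#' Every artefact-producing command records a JSON manifest holding the
#' command, package version, seed, config hash, output paths and an
#' ISO-8601 timestamp, making runs replayable.
#'
#' @param path Manifest path.
#' @param command Command name.
#' @param seed Seed used (or NULL).
#' @param config Config list used (or NULL); only its hash is stored.
#' @param outputs Character vector of artefact paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, seed = NULL, config = NULL,
                           outputs = character()) {
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("dutchpt")),
    seed = seed,
    config_hash = if (is.null(config)) NULL else config_hash(config),
    outputs = as.list(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest[!vapply(manifest, is.null, TRUE)], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
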