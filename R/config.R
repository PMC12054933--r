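#' Load a hierarchical experiment configuration
#'
#' Reads a YAML configuration file with sections `network`, `stdp`
#' (sub-sections `e`, `hi`, `ai` plus `gamma_l`, `lambda`, `M`, `f0`,
#' `f`), `protocol` and a top-level `seed`. Unspecified fields take the
#' reference defaults (see [network_params()] and [stdp_params()]);
#' unknown keys are an error (fail closed), as are inconsistent
#' population counts.
#'
#' @param path path to the YAML file, or `NULL` for pure defaults.
#' @return a list of class `qif_config` with elements `network`
#'   (a [network_params()]), `stdp` (an [stdp_params()]), `protocol`
#'   (list of schedule options) and `seed`.
#' @export
load_config <- function(path = NULL) {
  # keep YAML 1.1 boolean-like scalars (notably the key "N") as strings
  keep <- function(x) x
  raw <- if (is.null(path)) list() else
    yaml::read_yaml(path, handlers = list("bool#yes" = keep, "bool#no" = keep))
  if (is.null(raw)) raw <- list()
  known_top <- c("network", "stdp", "protocol", "seed")
  check_keys(raw, known_top, "top level")

  net_args <- raw$network
  check_keys(net_args, names(formals(network_params)), "network")
  params <- do.call(network_params, as_args(net_args))

  stdp_raw <- raw$stdp
  check_keys(stdp_raw, c("e", "hi", "ai", "gamma_l", "lambda", "M", "f0",
                         "f"), "stdp")
  top_args <- stdp_raw[intersect(names(stdp_raw),
                                 c("gamma_l", "lambda", "M", "f0", "f"))]
  stdp <- do.call(stdp_params, as_args(top_args))
  for (cl in c("e", "hi", "ai")) {
    ov <- stdp_raw[[cl]]
    check_keys(ov, names(stdp[[cl]]), paste0("stdp.", cl))
    stdp[[cl]] <- modifyList(stdp[[cl]], as_args(ov))
  }

  proto_defaults <- list(M = 2, mode = "random", n_epochs = 35, rest = 5,
                         consolidation = 20, stim_on = 0.8, epoch_len = 1,
                         overlap = 0, subset_fraction = 1,
                         amplitude_jitter = 0, untrained_fraction = 0,
                         regime = "mixed")
  check_keys(raw$protocol, names(proto_defaults), "protocol")
  protocol <- modifyList(proto_defaults, as_args(raw$protocol))

  structure(list(network = params, stdp = stdp, protocol = protocol,
                 seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed)),
            class = "qif_config")
}

check_keys <- function(x, known, where) {
  if (is.null(x)) return(invisible())
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
  invisible()
}

as_args <- function(x) if (is.null(x)) list() else x
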