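# Delimiter-separated text I/O for datasets and JSON serialisation of
# configurations.  Missing entries are written as empty fields so the
# missingness mask survives a round trip.

#' Write a (possibly incomplete) dataset as tab-separated text
#'
#' @param data Dataset with the canonical columns.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @export
write_dataset <- function(data, path, sep = "\t") {
  utils::write.table(data, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
}

#' Read a dataset written by [write_dataset()]
#'
#' Empty fields become `NA`, recovering the missingness mask.
#'
#' @param path Input file path.
#' @param sep Field separator (default tab).
#' @return Data frame with the file's columns.
#' @export
read_dataset <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep,
                    na.strings = "", stringsAsFactors = FALSE)
}

#' Serialise a configuration object to JSON
#'
#' Works for `population_config`, `amputation_config`,
#' `imputation_config` and `study_config` objects; the class is stored
#' so [read_config()] can restore it.
#'
#' @param config Configuration object.
#' @param path Output file path.
#' @export
write_config <- function(config, path) {
  # named atomic vectors become JSON objects (name -> value) so names
  # survive the round trip
  listify <- function(x) {
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    if (is.list(x) && !inherits(x, "population_config")) {
      return(lapply(x, listify))
    }
    if (inherits(x, "population_config")) return(lapply(unclass(x), listify))
    x
  }
  payload <- list(class = class(config)[1],
                  fields = lapply(unclass(config), listify))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

#' Read a configuration written by [write_config()]
#'
#' @param path Input file path.
#' @return Configuration object of the stored class.
#' @export
read_config <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  fields <- payload$fields
  cls <- payload$class
  if (cls == "population_config") {
    fields$binary_marginals <- unlist(fields$binary_marginals)
    fields$beta_gen <- unlist(fields$beta_gen)
    fields$censoring <- unlist(fields$censoring)
    if (is.data.frame(fields$association_targets)) {
      at <- fields$association_targets
      fields$association_targets <- lapply(seq_len(nrow(at)), function(i) {
        list(pair = unlist(at$pair[i]), phi = at$phi[i])
      })
    }
    return(do.call(population_config, fields))
  }
  if (cls == "amputation_config") {
    fields$mar_weights <- unlist(fields$mar_weights)
    return(do.call(amputation_config, fields))
  }
  if (cls == "imputation_config") return(do.call(imputation_config, fields))
  if (cls == "study_config") {
    pop <- fields$population
    pop$binary_marginals <- unlist(pop$binary_marginals)
    pop$beta_gen <- unlist(pop$beta_gen)
    pop$censoring <- unlist(pop$censoring)
    if (is.data.frame(pop$association_targets)) {
      at <- pop$association_targets
      pop$association_targets <- lapply(seq_len(nrow(at)), function(i) {
        list(pair = unlist(at$pair[i]), phi = at$phi[i])
      })
    }
    fields$population <- do.call(population_config, pop)
    return(do.call(study_config, fields))
  }
  stop("unknown config class: ", cls)
}

#' Serialise a Cox fit to JSON
#'
#' @param fit A `cox_fit`.
#' @param path Output file path.
#' @export
write_cox_fit <- function(fit, path) {
  payload <- list(beta = as.list(fit$beta), se = as.list(fit$se),
                  vcov = fit$vcov, loglik_null = fit$loglik_null,
                  loglik_fit = fit$loglik_fit, n = fit$n,
                  n_events = fit$n_events, converged = fit$converged)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}
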