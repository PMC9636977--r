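#' File formats
#'
#' Plain-text interchange formats, all round-trip lossless for finite doubles
#' (numbers are written with 17 significant digits):
#'
#' * interference edge list — TSV with header `source<TAB>target<TAB>gamma`,
#'   endpoints given as external ids;
#' * individual parameters — CSV `id,alpha,beta`;
#' * contagion peer weights — the same TSV dialect with column `c`, plus a
#'   CSV `id,a,b` for the intrinsic parameters;
#' * cluster map — CSV `id,cluster`;
#' * experiment data — CSV `id,z,Y`;
#' * design configuration — YAML or JSON with fields
#'   `kind` (`bernoulli`/`crd`/`cluster`/`saturation`), `n`, and the
#'   kind-specific parameters `p`, `m`, `treated`, `saturations`, and
#'   `clusters` (either an inline list or the path of a cluster-map CSV,
#'   resolved relative to the config file).
#'
#' @name netTTE-io
NULL

fmt_num <- function(x) sprintf("%.17g", x)

#' Read / write a HANE model
#'
#' @param model a [hane_model()].
#' @param params_path CSV path for `id,alpha,beta`.
#' @param edges_path TSV path for `source,target,gamma` (external ids).
#' @return `write_hane()` returns the model invisibly; `read_hane()` returns
#'   a [hane_model()] whose internal indices follow the row order of the
#'   parameter file.
#' @name hane-io
NULL

#' @rdname hane-io
#' @export
write_hane <- function(model, params_path, edges_path) {
  params <- data.frame(id = model$ids,
                       alpha = fmt_num(model$alpha),
                       beta = fmt_num(model$beta))
  utils::write.table(params, params_path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  e <- model$edges
  out <- data.frame(source = model$ids[e$source],
                    target = model$ids[e$target],
                    gamma = fmt_num(e$gamma))
  utils::write.table(out, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(model)
}

#' @rdname hane-io
#' @export
read_hane <- function(params_path, edges_path = NULL) {
  params <- utils::read.csv(params_path, colClasses = c(id = "character"))
  if (!all(c("id", "alpha", "beta") %in% names(params))) {
    stop("parameter file must have header id,alpha,beta")
  }
  edges <- NULL
  if (!is.null(edges_path)) {
    raw <- utils::read.delim(edges_path,
                             colClasses = c(source = "character",
                                            target = "character"))
    if (!all(c("source", "target", "gamma") %in% names(raw))) {
      stop("edge file must have header source<TAB>target<TAB>gamma")
    }
    if (nrow(raw)) {
      src <- match(raw$source, params$id)
      tgt <- match(raw$target, params$id)
      if (anyNA(src) || anyNA(tgt)) {
        bad <- c(raw$source[is.na(src)], raw$target[is.na(tgt)])[1L]
        stop("edge endpoint '", bad, "' is not an id in the parameter file")
      }
      edges <- data.frame(source = src, target = tgt,
                          gamma = as.numeric(raw$gamma))
    }
  }
  hane_model(alpha = as.numeric(params$alpha),
             beta = as.numeric(params$beta),
             edges = edges, ids = params$id)
}

#' Read / write a linear contagion model
#'
#' @param cm a [contagion_model()].
#' @param params_path CSV path for `id,a,b`.
#' @param edges_path TSV path for `source,target,c` (external ids).
#' @name contagion-io
NULL

#' @rdname contagion-io
#' @export
write_contagion <- function(cm, params_path, edges_path) {
  params <- data.frame(id = cm$ids, a = fmt_num(cm$a), b = fmt_num(cm$b))
  utils::write.table(params, params_path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  out <- data.frame(source = cm$ids[cm$edges$source],
                    target = cm$ids[cm$edges$target],
                    c = fmt_num(cm$edges$c))
  utils::write.table(out, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(cm)
}

#' @rdname contagion-io
#' @export
read_contagion <- function(params_path, edges_path = NULL) {
  params <- utils::read.csv(params_path, colClasses = c(id = "character"))
  if (!all(c("id", "a", "b") %in% names(params))) {
    stop("parameter file must have header id,a,b")
  }
  edges <- NULL
  if (!is.null(edges_path)) {
    raw <- utils::read.delim(edges_path,
                             colClasses = c(source = "character",
                                            target = "character"))
    if (nrow(raw)) {
      src <- match(raw$source, params$id)
      tgt <- match(raw$target, params$id)
      if (anyNA(src) || anyNA(tgt)) stop("unknown id in peer-weight file")
      edges <- data.frame(source = src, target = tgt,
                          c = as.numeric(raw$c))
    }
  }
  contagion_model(a = as.numeric(params$a), b = as.numeric(params$b),
                  edges = edges, ids = params$id)
}

#' Read / write a cluster map
#'
#' @param clusters vector of cluster labels, named by (or aligned with) ids.
#' @param ids external identifiers.
#' @param path CSV path with header `id,cluster`.
#' @name cluster-io
NULL

#' @rdname cluster-io
#' @export
write_cluster_map <- function(clusters, ids, path) {
  utils::write.table(data.frame(id = ids, cluster = clusters), path,
                     sep = ",", quote = FALSE, row.names = FALSE)
  invisible(clusters)
}

#' @rdname cluster-io
#' @param order_ids optional id vector giving the individual order to align
#'   the cluster labels to (defaults to file order).
#' @export
read_cluster_map <- function(path, order_ids = NULL) {
  raw <- utils::read.csv(path, colClasses = c(id = "character"))
  if (!all(c("id", "cluster") %in% names(raw))) {
    stop("cluster map must have header id,cluster")
  }
  if (!is.null(order_ids)) {
    idx <- match(as.character(order_ids), raw$id)
    if (anyNA(idx)) stop("cluster map is missing some ids")
    raw <- raw[idx, ]
  }
  stats::setNames(raw$cluster, raw$id)
}

#' Read / write realized experiment data
#'
#' @param z,Y treatment and outcome vectors.
#' @param ids external identifiers.
#' @param path CSV path with header `id,z,Y`.
#' @name experiment-io
NULL

#' @rdname experiment-io
#' @export
write_experiment <- function(z, Y, ids, path) {
  utils::write.table(data.frame(id = ids, z = as.integer(z), Y = fmt_num(Y)),
                     path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname experiment-io
#' @export
read_experiment <- function(path) {
  raw <- utils::read.csv(path, colClasses = c(id = "character"))
  if (!all(c("id", "z", "Y") %in% names(raw))) {
    stop("experiment file must have header id,z,Y")
  }
  list(ids = raw$id, z = as.numeric(raw$z), Y = as.numeric(raw$Y))
}

# yaml 1.1 would otherwise read the bare key "n" as the boolean FALSE; keep
# single letters literal while still honoring true/false values.
read_config_file <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    return(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) if (tolower(x) %in% c("true", "yes", "on")) TRUE else x,
    "bool#no" = function(x) if (tolower(x) %in% c("false", "no", "off")) FALSE else x))
}

#' Read a scenario specification from YAML/JSON
#'
#' The file mirrors the arguments of [scenario_spec()]: top-level fields `n`,
#' `reps`, `seed` and blocks `network`, `alpha`, `beta`, `gamma`, `design`.
#'
#' @param path configuration file.
#' @return a [scenario_spec()].
#' @export
read_scenario <- function(path) {
  cfg <- read_config_file(path)
  defaults <- scenario_spec()
  scenario_spec(n = cfg$n %||% defaults$n,
                network = cfg$network %||% defaults$network,
                alpha = cfg$alpha %||% defaults$alpha,
                beta = cfg$beta %||% defaults$beta,
                gamma = cfg$gamma %||% defaults$gamma,
                design = cfg$design %||% defaults$design,
                reps = cfg$reps %||% defaults$reps,
                seed = cfg$seed %||% defaults$seed)
}

#' Read a design from a YAML/JSON configuration
#'
#' @param path configuration file; the extension selects the parser
#'   (`.json` vs `.yaml`/`.yml`).
#' @param order_ids optional id order for aligning a cluster-map file.
#' @return a `tte_design`.
#' @export
read_design_config <- function(path, order_ids = NULL) {
  cfg <- read_config_file(path)
  clusters <- cfg$clusters
  if (is.character(clusters) && length(clusters) == 1L) {
    cl_path <- clusters
    if (!file.exists(cl_path)) {
      cl_path <- file.path(dirname(path), clusters)
    }
    clusters <- read_cluster_map(cl_path, order_ids = order_ids)
  }
  n <- cfg$n %||% length(clusters)
  switch(cfg$kind,
    bernoulli = design_bernoulli(n, cfg$p),
    crd = design_crd(n, cfg$m %||% round(cfg$p * n)),
    cluster = design_cluster(clusters,
                             cfg$treated %||%
                               round(cfg$p * length(unique(clusters)))),
    saturation = design_saturation(clusters, unlist(cfg$saturations),
                                   budget = cfg$p),
    stop("unknown design kind in config: ", cfg$kind))
}
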