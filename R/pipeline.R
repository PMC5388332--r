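#' Run the full transform / cluster / project / evaluate pipeline
#'
#' One-call driver: normalizes the expression matrix, builds the
#' representation required by the chosen measure, clusters it with the
#' multi-restart K-means, projects it under the chosen family, computes S1
#' and S2 silhouettes, the D-plot series and the nearest-neighbor map, and
#' (optionally) writes the whole bundle plus a JSON run manifest to a
#' directory.  Given the same configuration and seed the bundle is fully
#' deterministic.
#'
#' @param x raw expression matrix, or a path readable by
#'   [read_expression_matrix()].
#' @param measure measure name for [dissimilarity_model()].
#' @param k number of clusters.
#' @param family projection family for [project_expression()].
#' @param restarts K-means restart budget.
#' @param seed integer seed used for every stochastic stage.
#' @param dplot_k neighborhood limit for [d_plots()].
#' @param out_dir optional output directory; created if missing.
#' @return (invisibly when writing) a list with `clustering`, `projection`,
#'   `s1`, `s2`, `dplot`, `neighbors`, `config`, and `files` when written.
#' @export
pipeline_run <- function(x, measure = "pccf", k = 7L, family = "pca-f",
                         restarts = 100L, seed = 1L, dplot_k = 20L,
                         out_dir = NULL) {
  if (is.character(x) && length(x) == 1L) x <- read_expression_matrix(x)
  model <- dissimilarity_model(measure)
  config <- list(measure = model$name, k = as.integer(k),
                 family = tolower(family), restarts = as.integer(restarts),
                 seed = as.integer(seed), dplot_k = as.integer(dplot_k),
                 genes = nrow(x), time_points = ncol(x))
  message("fpcc: transform [", model$representation, "]")
  rep_data <- model_representation(model, x)
  message("fpcc: cluster [", model$name, ", k = ", k, ", restarts = ",
          restarts, "]")
  clustering <- km_fit(rep_data, model, k, restarts = restarts, seed = seed)
  clustering <- relabel_by_size(clustering)
  message("fpcc: project [", config$family, "]")
  projection <- project_expression(x, config$family)
  message("fpcc: evaluate")
  s1 <- silhouette_s1(rep_data, clustering, model)
  s2 <- silhouette_s2(rep_data, projection, model, k = k,
                      restarts = restarts, seed = seed)
  dplot <- d_plots(rep_data, projection, k = min(dplot_k, nrow(x) - 1L))
  neighbors <- neighbor_map(rep_data, model, scores = projection)
  out <- list(clustering = clustering, projection = projection,
              s1 = s1, s2 = s2, dplot = dplot, neighbors = neighbors,
              config = config)
  if (is.null(out_dir)) return(out)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(name) file.path(out_dir, name)
  write.table(data.frame(gene = names(clustering$labels),
                         cluster = as.integer(clustering$labels)),
              fp("labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  sc <- projection$scores
  sdf <- data.frame(gene = rownames(sc), comp1 = sc[, 1], comp2 = sc[, 2])
  writeLines(c(sprintf("# family=%s var1=%.6f var2=%.6f",
                       projection$family, projection$variance_fraction[1],
                       projection$variance_fraction[2]),
               paste(names(sdf), collapse = "\t"),
               do.call(paste, c(lapply(sdf, format, trim = TRUE,
                                       digits = 15), sep = "\t"))),
             fp("scores.tsv"))
  write.table(data.frame(variant = c("S1", "S2"),
                         s_value = c(s1$s_value, s2$s_value),
                         measure = model$name, k = k),
              fp("svalues.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dplot, fp("dplot.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(neighbors, fp("neighbors.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c("labels.tsv", "scores.tsv", "svalues.tsv", "dplot.tsv",
             "neighbors.tsv")
  manifest <- list(package = "fpcc",
                   version = as.character(packageVersion("fpcc")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   config = config,
                   config_hash = config_hash(config),
                   files = files)
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  out$files <- file.path(out_dir, c(files, "manifest.json"))
  invisible(out)
}

# small stable polynomial hash of the deparsed configuration
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}
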