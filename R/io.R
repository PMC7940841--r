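#' Read a genes-by-samples expression matrix
#'
#' Reads delimited text with a header row of sample identifiers and a first
#' column of gene identifiers. The delimiter (tab or comma) is detected from
#' the header line. Duplicate gene identifiers, ragged rows, empty files and
#' non-numeric cells raise descriptive errors.
#'
#' @param path file path.
#' @param transpose set to TRUE for files with samples in rows; the returned
#'   matrix is always genes x samples.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  if (length(header) == 0) stop("empty file: ", path, call. = FALSE)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("matrix file must have at least one gene row and one sample column",
         call. = FALSE)
  }
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  M <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (any(is.na(M) & !is.na(vals))) {
    bad <- which(is.na(M) & !is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                 ids[bad[1]], colnames(vals)[bad[2]]), call. = FALSE)
  }
  if (anyNA(M)) stop("matrix contains missing values", call. = FALSE)
  dimnames(M) <- list(ids, colnames(vals))
  if (transpose) M <- t(M)
  M
}

#' Write an expression matrix
#'
#' Tab-separated, sample identifiers as the header, gene identifiers as the
#' first column; the exact inverse of [read_expression_matrix()].
#'
#' @param M numeric matrix with dimnames.
#' @param path output path.
#' @export
write_expression_matrix <- function(M, path) {
  df <- data.frame(id = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample labels
#'
#' Two-column tab-separated file: sample identifier, class label.
#'
#' @param path file path.
#' @return Named character vector of labels (names are sample identifiers).
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) stop("labels file needs columns: sample, label", call. = FALSE)
  stats::setNames(df[[2]], df[[1]])
}

#' @rdname read_labels
#' @param labels vector of labels; names (or positions) identify samples.
#' @param sample_ids identifiers to use when `labels` is unnamed.
#' @export
write_labels <- function(labels, path, sample_ids = names(labels)) {
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_along(labels))
  utils::write.table(
    data.frame(sample = sample_ids, label = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

run_config_fields <- c(
  "k", "p", "lambda", "alpha", "mu0", "rho", "k_neighbors", "scheme",
  "max_iter", "tol", "mu_max", "v_update", "seed",
  "input", "labels", "out_dir", "log2_transform", "standardize_genes",
  "n_runs", "network_threshold", "n_top_genes"
)

#' Pipeline run configuration
#'
#' All solver hyperparameters plus paths, preprocessing flags, evaluation
#' restart count, and network settings, with strict validation: unknown
#' fields are rejected and a serialize/deserialize round trip is the
#' identity.
#'
#' @param input path to the expression matrix (may be NA when `X` is passed
#'   to [run_pipeline()] directly).
#' @param labels path to a labels file, or NA to skip evaluation.
#' @param out_dir output directory.
#' @param log2_transform apply log2(x + 1) before fitting (default FALSE).
#' @param standardize_genes standardize each gene row to zero mean and unit
#'   variance before fitting (default FALSE).
#' @param n_runs K-means restarts for evaluation (default 50).
#' @param network_threshold edge cutoff tau for the co-expression network
#'   (default 0.8).
#' @param n_top_genes number of top-ranked genes in the network (default
#'   500, capped at the number of genes).
#' @inheritParams pl21gpca_config
#' @return Object of class `run_config` (a validated named list).
#' @export
run_config <- function(k, input = NA_character_, labels = NA_character_,
                       out_dir = ".", p = 0.5, lambda = 100, alpha = 100,
                       mu0 = 1e-2, rho = 1.2, k_neighbors = NULL,
                       scheme = "binary", max_iter = 500, tol = 1e-7,
                       mu_max = 1e7, v_update = "with_A", seed = 0L,
                       log2_transform = FALSE, standardize_genes = FALSE,
                       n_runs = 50, network_threshold = 0.8,
                       n_top_genes = 500) {
  solver <- pl21gpca_config(k = k, p = p, lambda = lambda, alpha = alpha,
                            mu0 = mu0, rho = rho, k_neighbors = k_neighbors,
                            scheme = scheme, max_iter = max_iter, tol = tol,
                            mu_max = mu_max, v_update = v_update, seed = seed)
  cfg <- c(unclass(solver),
           list(input = as.character(input), labels = as.character(labels),
                out_dir = as.character(out_dir),
                log2_transform = isTRUE(log2_transform),
                standardize_genes = isTRUE(standardize_genes),
                n_runs = as.integer(n_runs),
                network_threshold = as.numeric(network_threshold),
                n_top_genes = as.integer(n_top_genes)))
  structure(cfg[run_config_fields], class = "run_config")
}

#' Serialize / deserialize a run configuration
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), run_config_fields)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(c("k"), names(raw))
  if (length(missing)) stop("config lacks required field `k`", call. = FALSE)
  raw <- lapply(raw, function(x) if (is.null(x)) NA else x)
  if (!is.null(raw$k_neighbors) && all(is.na(raw$k_neighbors))) {
    raw$k_neighbors <- NULL
    do.call(run_config, raw)
  } else {
    do.call(run_config, raw)
  }
}

solver_config_of <- function(config) {
  do.call(pl21gpca_config,
          unclass(config)[c("k", "p", "lambda", "alpha", "mu0", "rho",
                            "k_neighbors", "scheme", "max_iter", "tol",
                            "mu_max", "v_update", "seed")])
}

#' Run the full analysis pipeline
#'
#' Graph construction, model fit, K-means evaluation (when labels are given),
#' gene ranking, and co-expression network extraction, writing every artifact
#' to `config$out_dir`: `U.tsv`, `V.tsv`, `diagnostics.json`,
#' `clustering_report.json`, `edges.tsv`, `modules.tsv`, `degrees.tsv`,
#' `config.json` and `run.log`. Reruns with the same configuration and seed
#' produce identical outputs.
#'
#' @param config a [run_config()].
#' @param X optional in-memory genes x samples matrix (overrides
#'   `config$input`).
#' @param prior optional label vector (overrides `config$labels`).
#' @return Invisibly, a list with the fit, the report (or NULL), the ranking
#'   and the network.
#' @export
run_pipeline <- function(config, X = NULL, prior = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat("", file = logf)
  stage <- "read input"
  result <- tryCatch({
    if (is.null(X)) {
      if (is.na(config$input)) {
        stop("no input matrix: set `input` in the config or pass `X`")
      }
      X <- read_expression_matrix(config$input)
    }
    if (is.null(prior) && !is.na(config$labels)) {
      lab <- read_labels(config$labels)
      if (!all(colnames(X) %in% names(lab))) {
        stop("labels file does not cover all samples")
      }
      prior <- lab[colnames(X)]
    }
    log_line("input: %d genes x %d samples", nrow(X), ncol(X))
    cfg_str <- paste(format(unclass(config)), collapse = "|")
    log_line("config hash: %08x",
             sum(utf8ToInt(cfg_str) * seq_along(utf8ToInt(cfg_str))) %% 2^31)
    log_line("seed: %d", config$seed)

    stage <- "preprocess"
    if (config$log2_transform) X <- log2(X + 1)
    if (config$standardize_genes) {
      s <- apply(X, 1, stats::sd)
      X <- (X - rowMeans(X)) / ifelse(s > 0, s, 1)
    }

    stage <- "graph"
    scfg <- solver_config_of(config)
    graph <- if (scfg$alpha != 0) {
      sample_graph(X, k_neighbors = scfg$k_neighbors, scheme = scfg$scheme)
    } else NULL
    if (!is.null(graph)) {
      log_line("graph: k' = %d, scheme = %s", graph$k_neighbors, graph$scheme)
    }

    stage <- "fit"
    fit <- pl21gpca_fit(X, scfg, graph)
    log_line("fit: %d sweeps, converged = %s, final residual = %.3g",
             fit$n_iter, fit$converged, utils::tail(fit$residual_trace, 1))
    rownames(fit$U) <- rownames(X)
    rownames(fit$V) <- colnames(X)
    write_expression_matrix(fit$U, file.path(config$out_dir, "U.tsv"))
    write_expression_matrix(fit$V, file.path(config$out_dir, "V.tsv"))
    jsonlite::write_json(
      list(n_iter = fit$n_iter, converged = fit$converged,
           residual_trace = fit$residual_trace,
           objective_trace = fit$objective_trace,
           ortho_trace = fit$ortho_trace,
           config = unclass(config)),
      file.path(config$out_dir, "diagnostics.json"),
      auto_unbox = TRUE, digits = NA, na = "null")

    stage <- "evaluate"
    report <- NULL
    if (!is.null(prior)) {
      report <- kmeans_harness(fit$V, scfg$k, prior, n_runs = config$n_runs,
                               seed = config$seed)
      log_line("evaluation: ACC_mean = %.2f%%, NMI_mean = %.2f%%",
               report$acc_mean, report$nmi_mean)
      jsonlite::write_json(
        list(acc_max = report$acc_max, acc_mean = report$acc_mean,
             nmi_max = report$nmi_max, nmi_mean = report$nmi_mean,
             n_runs = report$n_runs, per_run = report$per_run),
        file.path(config$out_dir, "clustering_report.json"),
        auto_unbox = TRUE, digits = NA)
    }

    stage <- "gene network"
    ranking <- rank_genes(fit$U)
    l <- min(config$n_top_genes, nrow(X))
    top <- ranking$order[seq_len(l)]
    A <- pcc_adjacency(X[top, , drop = FALSE], config$network_threshold)
    net <- extract_modules(A)
    log_line("network: %d genes, %d edges, %d modules", l, net$n_edges,
             length(net$modules))
    write_edge_list(A, file.path(config$out_dir, "edges.tsv"))
    mod_df <- if (length(net$modules)) {
      data.frame(
        gene = unlist(net$module_ids),
        module = rep(seq_along(net$modules), lengths(net$modules)))
    } else data.frame(gene = character(), module = integer())
    utils::write.table(mod_df, file.path(config$out_dir, "modules.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(gene = names(net$degrees), degree = net$degrees),
      file.path(config$out_dir, "degrees.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)

    write_run_config(config, file.path(config$out_dir, "config.json"))
    log_line("done")
    list(fit = fit, report = report, ranking = ranking, network = net)
  }, error = function(e) {
    log_line("FAILED at stage '%s': %s", stage, conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
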