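.default_config <- function() {
  list(internal = NULL, external = NULL, name = "dataset",
       delimiter = "\t", log2 = FALSE, center = FALSE,
       m1 = NA, m2 = NA, variance_target = 0.98, external_lags = 1,
       unit_tol = 1e-6, real_tol = 1e-9, pinv_rtol = 1e-10,
       seed = 1, out_dir = "ssdyn_out")
}

#' Read a flat key = value run configuration
#'
#' One \code{key = value} pair per line; \code{#} starts a comment. Unknown
#' keys error. Every numeric tolerance has an explicit default and all
#' effective values (given or defaulted) are echoed into the run manifest.
#'
#' @param path Path to the config file.
#' @return A named list merging the file over the defaults.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- sub("#.*$", "", sub("\r$", "", readLines(path, warn = FALSE)))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- .default_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    cfg[[key]] <- if (key %in% c("log2", "center")) {
      toupper(val) %in% c("TRUE", "T", "YES", "1")
    } else if (key %in% c("internal", "external", "name", "out_dir",
                          "delimiter")) {
      val
    } else suppressWarnings(as.numeric(val))
  }
  bad <- c("unit_tol", "real_tol", "pinv_rtol")[
    c(cfg$unit_tol, cfg$real_tol, cfg$pinv_rtol) <= 0]
  if (length(bad)) stop("tolerances must be positive: ", paste(bad, collapse = ", "))
  cfg
}

.write_tsv <- function(mat, path, row_label = "id") {
  mat <- as.matrix(mat)
  con <- file(path, "w")
  on.exit(close(con))
  cn <- colnames(mat)
  if (is.null(cn)) cn <- as.character(seq_len(ncol(mat)))
  rn <- rownames(mat)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(mat)))
  writeLines(paste(c(row_label, cn), collapse = "\t"), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(c(rn[i], sprintf("%.17g", mat[i, ])), collapse = "\t"),
               con)
  }
  invisible(path)
}

.pdp_json <- function(p) {
  out <- list(kind = p$kind, index = p$index,
              is_merged_conjugate = p$is_merged_conjugate,
              trajectory = unname(p$trajectory),
              trajectory_unit = unname(p$trajectory_unit))
  if (p$kind == "iPDP") {
    out$eigenvalue_re <- Re(p$eigenvalue)
    out$eigenvalue_im <- Im(p$eigenvalue)
    out$class_label <- as.character(p$class_label)
    per <- attr(p$class_label, "period")
    if (!is.null(per)) out$oscillation_period <- per
  }
  out
}

#' Run the full decomposition pipeline and write its artifacts
#'
#' Executes the five stages — load, metagene projection, model estimation,
#' pattern extraction, gene coefficients — and writes every artifact plus a
#' manifest as delimited text / JSON. Output is a pure function of (input
#' files, config, seed): reruns with the same config are bitwise identical.
#' Stage timings are logged to stderr only, never into artifacts.
#'
#' @param config A config list (see [read_run_config()]) or a path to a
#'   flat key = value config file. Alternatively pass \code{dataset} to
#'   skip the load stage.
#' @param dataset Optional pre-assembled [expression_dataset()]; overrides
#'   the \code{internal}/\code{external} paths in the config.
#' @return The manifest, invisibly: config used (with every default
#'   tolerance explicit), stages completed, artifact files with md5 hashes
#'   and package version.
#' @export
run_pipeline <- function(config, dataset = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(.default_config(), config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
    message(sprintf("stage %-12s %.2fs", stage,
                    proc.time()[["elapsed"]] - t0))
    stages <<- c(stages, stage)
    res
  }
  set.seed(as.integer(cfg$seed))

  ds <- run_stage("load", {
    if (!is.null(dataset)) dataset
    else {
      if (is.null(cfg$internal) || is.null(cfg$external)) {
        stop("config must provide internal and external matrix paths")
      }
      expression_dataset(
        read_expression_matrix(cfg$internal, cfg$delimiter),
        read_expression_matrix(cfg$external, cfg$delimiter),
        name = cfg$name, log2 = cfg$log2, center = cfg$center)
    }
  })

  bases <- run_stage("metagenes", {
    m1 <- if (is.na(cfg$m1)) NULL else as.integer(cfg$m1)
    m2 <- if (is.na(cfg$m2)) NULL else as.integer(cfg$m2)
    if (is.null(m1)) m1 <- choose_dimension(ds$internal_matrix,
                                            cfg$variance_target,
                                            partner_M = 1L)$M
    if (is.null(m2)) m2 <- choose_dimension(ds$external_matrix,
                                            cfg$variance_target,
                                            partner_M = m1)$M
    list(internal = fit_metagenes(ds$internal_matrix, m1, "internal"),
         external = fit_metagenes(ds$external_matrix, m2, "external"))
  })

  model <- run_stage("estimate", {
    estimate_model(bases$internal$scores, bases$external$scores,
                   rtol = cfg$pinv_rtol)
  })

  pats <- run_stage("patterns", {
    dec <- decompose_dynamics(model, bases$internal$scores[, 1L],
                              bases$external$scores,
                              external_lags = cfg$external_lags)
    list(decomposition = dec,
         ipdps = extract_ipdps(model$A_tilde, bases$internal$scores[, 1L],
                               ds$T, unit_tol = cfg$unit_tol,
                               real_tol = cfg$real_tol),
         epdps = extract_epdps(model$B_tilde, bases$external$scores))
  })

  coefs <- run_stage("coefficients", {
    list(ipdp = gene_coefficients_ipdp(bases$internal, pats$ipdps),
         epdp = gene_coefficients_epdp(bases$internal, model$B_tilde))
  })

  # -- artifacts ------------------------------------------------------------
  art <- c(
    W_internal = "W_internal.tsv", W_external = "W_external.tsv",
    scores_internal = "scores_internal.tsv",
    scores_external = "scores_external.tsv",
    A_tilde = "A_tilde.tsv", B_tilde = "B_tilde.tsv",
    component_internal = "component_internal.tsv",
    component_external = "component_external.tsv",
    component_interaction = "component_interaction.tsv",
    gene_coefficients_ipdp = "gene_coefficients_ipdp.tsv",
    gene_coefficients_epdp = "gene_coefficients_epdp.tsv",
    patterns = "patterns.json")
  fp <- function(f) file.path(out_dir, f)
  .write_tsv(bases$internal$W, fp(art["W_internal"]), "gene_id")
  .write_tsv(bases$external$W, fp(art["W_external"]), "gene_id")
  .write_tsv(bases$internal$scores, fp(art["scores_internal"]), "metagene")
  .write_tsv(bases$external$scores, fp(art["scores_external"]), "metagene")
  .write_tsv(model$A_tilde, fp(art["A_tilde"]), "row")
  .write_tsv(model$B_tilde, fp(art["B_tilde"]), "row")
  .write_tsv(pats$decomposition$internal, fp(art["component_internal"]), "metagene")
  .write_tsv(pats$decomposition$external, fp(art["component_external"]), "metagene")
  .write_tsv(pats$decomposition$interaction, fp(art["component_interaction"]), "metagene")
  .write_tsv(coefs$ipdp$magnitude, fp(art["gene_coefficients_ipdp"]), "gene_id")
  .write_tsv(coefs$epdp$signed, fp(art["gene_coefficients_epdp"]), "gene_id")
  jsonlite::write_json(
    list(ipdps = lapply(pats$ipdps, .pdp_json),
         epdps = lapply(pats$epdps, .pdp_json)),
    fp(art["patterns"]), auto_unbox = TRUE, digits = NA)

  cfg_txt <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 17L), collapse = ","), character(1L)),
    sep = "=", collapse = "\n")
  manifest <- list(
    package = "ssdyn",
    package_version = as.character(utils::packageVersion("ssdyn")),
    config = cfg[order(names(cfg))],
    config_hash = .text_md5(cfg_txt),
    seed = cfg$seed,
    dataset = list(name = ds$name, N1 = length(ds$internal_ids),
                   N2 = length(ds$external_ids), T = ds$T,
                   M1 = bases$internal$M, M2 = bases$external$M),
    diagnostics = list(
      explained_internal = bases$internal$explained_fraction,
      explained_external = bases$external$explained_fraction,
      residual_norm = model$residual_norm,
      rank_upsilon = model$rank_upsilon,
      conservation_check = pats$decomposition$total_check),
    stages = stages,
    artifacts = lapply(stats::setNames(as.list(art), names(art)), function(f)
      list(file = f, md5 = unname(tools::md5sum(fp(f))))))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

.text_md5 <- function(txt) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}
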