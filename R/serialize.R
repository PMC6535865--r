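#' Write a factorization to a directory
#'
#' Emits `W.tsv`, `H.tsv`, `trace.tsv` and `meta.json` (solver name, rank,
#' convergence flag, iteration count, solver configuration).
#'
#' @param fit An `amnd_factorization`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_factorization <- function(fit, dir) {
  stopifnot(inherits(fit, "amnd_factorization"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  W <- fit$W
  if (is.null(rownames(W))) rownames(W) <- sprintf("S%04d", seq_len(nrow(W)))
  colnames(W) <- sprintf("f%03d", seq_len(ncol(W)))
  write_matrix(W, file.path(dir, "W.tsv"))
  H <- fit$H
  rownames(H) <- sprintf("f%03d", seq_len(nrow(H)))
  if (is.null(colnames(H))) colnames(H) <- sprintf("g%05d", seq_len(ncol(H)))
  write_matrix(H, file.path(dir, "H.tsv"))
  write.table(data.frame(iteration = seq_along(fit$objective_trace) - 1L,
                         objective = fit$objective_trace),
              file.path(dir, "trace.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- list(solver_name = fit$solver_name, r = fit$r,
               converged = fit$converged, iterations = fit$iterations,
               config = unclass(fit$config))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a factorization written by [write_factorization()]
#'
#' @param dir Directory with `W.tsv`, `H.tsv`, `trace.tsv`, `meta.json`.
#' @return An `amnd_factorization`.
#' @export
read_factorization <- function(dir) {
  W <- read_matrix(file.path(dir, "W.tsv"), "expression")
  H <- read_matrix(file.path(dir, "H.tsv"), "expression")
  trace <- read.table(file.path(dir, "trace.tsv"), header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  cfg <- do.call(solver_config, meta$config[setdiff(names(meta$config), NULL)])
  new_factorization(W, H, meta$solver_name, trace$objective,
                    isTRUE(meta$converged), cfg)
}
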