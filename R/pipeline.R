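# One-call pipeline driver and batch mode; also the engine behind the
# command-line interface in exec/gnmkit.

.exit_codes <- c(ok = 0L, rejected = 2L, disconnected = 3L,
                 parse_error = 4L, io_error = 5L)

#' Run the full analysis pipeline on one structure
#'
#' Executes parse -> assembly -> node selection -> admission -> Kirchhoff ->
#' eigendecomposition -> analysis -> plain-text report for a single PDB
#' file. Failures abort the pipeline at the first failing stage and are
#' classified into distinct exit codes (0 ok, 2 rejected by admission,
#' 3 disconnected network, 4 parse error, 5 I/O error). On failure the
#' output directory contains only a `failure.json` record, never a partial
#' bundle.
#'
#' @param input Path to a PDB file.
#' @param output_dir Directory for the result bundle (see
#'   [write_report()]); `NULL` computes without writing.
#' @param assembly `"asymmetric"`, `"first_assembly"`, or an assembly
#'   index.
#' @param cutoff Contact cutoff r_c in Angstrom.
#' @param model Model number retained from multi-model files.
#' @param store_fraction,n_fast,soft_subset,scale_policy Report options,
#'   see [write_report()].
#' @param min_nodes,max_nodes,calpha_only_filter Admission options, see
#'   [admit_structure()].
#' @param protein_only_b Restrict the B-factor comparison to protein nodes.
#' @param verbose Log stages to stderr.
#' @return A list of class `gnm_run` with `status` (one of `"ok"`,
#'   `"rejected"`, `"disconnected"`, `"parse_error"`, `"io_error"`),
#'   `exit_code`, `message`, and on success `summary` plus the computed
#'   objects (`nodes`, `kirchhoff`, `modes`, `profile`).
#' @export
gnm_run <- function(input, output_dir = NULL,
                    assembly = "asymmetric", cutoff = 7.3, model = 1,
                    store_fraction = 0.4, n_fast = 10L, soft_subset = 1:3,
                    min_nodes = 12, max_nodes = 20000,
                    calpha_only_filter = TRUE,
                    scale_policy = c("fit", "unit"),
                    protein_only_b = FALSE, verbose = FALSE) {
  scale_policy <- match.arg(scale_policy)
  say <- function(...) if (verbose) message("[gnmkit] ", ...)
  fail <- function(status, msg) {
    if (!is.null(output_dir)) {
      unlink(output_dir, recursive = TRUE)
      dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(list(status = status, message = msg,
                                input = input),
                           file.path(output_dir, "failure.json"),
                           auto_unbox = TRUE)
    }
    out <- list(status = status, exit_code = .exit_codes[[status]],
                message = msg)
    class(out) <- "gnm_run"
    out
  }

  t0 <- proc.time()[3]
  s <- tryCatch(read_structure(input, model = model),
                error = function(e) e)
  if (inherits(s, "error")) return(fail("parse_error", conditionMessage(s)))
  say("parsed ", nrow(s$atom), " atoms from ", input)

  if (!identical(assembly, "asymmetric")) {
    s <- tryCatch(build_assembly(s, assembly), error = function(e) e)
    if (inherits(s, "error")) return(fail("parse_error", conditionMessage(s)))
    say("assembly built: ", length(unique(s$atom$chain)), " chain(s)")
  }

  nodes <- tryCatch(select_nodes(s), error = function(e) e)
  if (inherits(nodes, "error"))
    return(fail("rejected", conditionMessage(nodes)))
  say("selected ", gnm_n_nodes(nodes), " nodes")

  adm <- admit_structure(nodes, s, min_nodes = min_nodes,
                         max_nodes = max_nodes,
                         calpha_only_filter = calpha_only_filter)
  if (!adm$accepted) return(fail("rejected", adm$reason))

  k <- suppressWarnings(build_kirchhoff(nodes, cutoff = cutoff))
  modes <- gnm_modes(k)
  if (modes$n_zero > 1) {
    comps <- connected_components(k)
    return(fail("disconnected",
                paste0(length(comps), " components of sizes ",
                       paste(head(lengths(comps), 10), collapse = ", "))))
  }
  profile <- gnm_profile(modes)
  say("decomposed: ", n_nonzero(modes), " nonzero modes in ",
      round(proc.time()[3] - t0, 2), " s")

  b_for_r <- nodes$b
  if (protein_only_b) b_for_r[nodes$node_class != "protein"] <- NA_real_
  nodes_r <- nodes
  nodes_r$b <- b_for_r

  summary <- NULL
  if (!is.null(output_dir)) {
    summary <- tryCatch(
      write_report(output_dir, s, nodes_r, k, modes, profile,
                   store_fraction = store_fraction, n_fast = n_fast,
                   soft_subset = soft_subset, scale_policy = scale_policy),
      error = function(e) e)
    if (inherits(summary, "error"))
      return(fail("io_error", conditionMessage(summary)))
    say("bundle written to ", output_dir)
  }
  out <- list(status = "ok", exit_code = 0L, message = "",
              summary = summary, structure = s, nodes = nodes,
              kirchhoff = k, modes = modes, profile = profile)
  class(out) <- "gnm_run"
  out
}

#' @export
print.gnm_run <- function(x, ...) {
  if (x$status == "ok")
    cat("gnm_run: ok -", x$modes$n, "nodes,", n_nonzero(x$modes),
        "nonzero modes\n")
  else
    cat("gnm_run:", x$status, "-", x$message, "\n")
  invisible(x)
}

#' Run the pipeline over a batch of structures
#'
#' Processes each input independently (a failure in one row never stops the
#' batch) and returns a relational summary table with one row per input:
#' node count, chain count, axial ratio, B-factor correlation (`NA` when no
#' usable experimental B-factors exist) and the admission/failure verdict.
#'
#' @param inputs Character vector of PDB paths, or a data frame with
#'   columns `input` and optionally `id` and `assembly`.
#' @param output_root Optional directory; when given, each input's bundle
#'   is written under `<output_root>/<id>/`.
#' @param export Optional path prefix; writes `<export>.tsv` and
#'   `<export>.csv` copies of the table.
#' @param ... Further arguments passed to [gnm_run()].
#' @return Data frame with columns `id`, `status`, `n_nodes`, `n_chains`,
#'   `axial_ratio`, `r_bfactor`, `verdict`.
#' @export
gnm_batch <- function(inputs, output_root = NULL, export = NULL, ...) {
  if (is.character(inputs))
    inputs <- data.frame(input = inputs, stringsAsFactors = FALSE)
  if (!nrow(inputs)) stop("usage error: empty batch manifest")
  if (is.null(inputs$id))
    inputs$id <- sub("\\.pdb$", "", basename(inputs$input))

  rows <- lapply(seq_len(nrow(inputs)), function(i) {
    args <- list(input = inputs$input[i], ...)
    if (!is.null(inputs$assembly)) args$assembly <- inputs$assembly[i]
    if (!is.null(output_root))
      args$output_dir <- file.path(output_root, inputs$id[i])
    res <- tryCatch(do.call(gnm_run, args),
                    error = function(e)
                      list(status = "io_error",
                           message = conditionMessage(e)))
    if (identical(res$status, "ok")) {
      shape <- axial_ratio(res$nodes)
      r_b <- tryCatch(bfactor_correlation(res$profile$msf, res$nodes$b),
                      error = function(e) NA_real_)
      data.frame(id = inputs$id[i], status = "ok",
                 n_nodes = res$modes$n,
                 n_chains = length(unique(res$nodes$label$chain)),
                 axial_ratio = shape$axial_ratio, r_bfactor = r_b,
                 verdict = "ok", stringsAsFactors = FALSE)
    } else {
      data.frame(id = inputs$id[i], status = res$status,
                 n_nodes = NA_integer_, n_chains = NA_integer_,
                 axial_ratio = NA_real_, r_bfactor = NA_real_,
                 verdict = paste0(res$status, ": ", res$message),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (!is.null(export)) {
    write_tsv_det(out, paste0(export, ".tsv"))
    utils::write.csv(out, paste0(export, ".csv"), row.names = FALSE)
  }
  out
}
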