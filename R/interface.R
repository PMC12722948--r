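# Configuration, serialization and the end-to-end pipeline.

#' Serialize a complex matrix to a JSON-friendly list
#'
#' Matrices travel in reports as nested lists of `[re, im]` pairs, written
#' with 17 significant digits so a write-read round trip is exact.
#'
#' @param M numeric or complex matrix.
#' @return Nested list (rows of `[re, im]` pairs).
#' @export
matrix_to_reim <- function(M) {
  M <- as_complex_matrix(M)
  lapply(seq_len(nrow(M)), function(i) {
    lapply(seq_len(ncol(M)), function(j) c(Re(M[i, j]), Im(M[i, j])))
  })
}

#' Rebuild a complex matrix from its `[re, im]` list form
#'
#' @param x nested list as produced by [matrix_to_reim()] (or its parsed
#'   JSON image).
#' @return Complex matrix.
#' @export
reim_to_matrix <- function(x) {
  n <- length(x)
  m <- length(x[[1]])
  out <- matrix(0i, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      p <- unlist(x[[i]][[j]])
      out[i, j] <- complex(real = p[1], imaginary = p[2])
    }
  }
  out
}

#' Write / read a complex matrix as JSON
#'
#' @param M matrix to write.
#' @param path file path.
#' @return `write_matrix_json` returns `path` invisibly; `read_matrix_json`
#'   returns the matrix.
#' @export
write_matrix_json <- function(M, path) {
  jsonlite::write_json(matrix_to_reim(M), path, digits = I(17),
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_matrix_json
#' @export
read_matrix_json <- function(path) {
  reim_to_matrix(jsonlite::read_json(path))
}

#' Read multichannel signals from delimited text
#'
#' Channels are rows, samples are columns (the EEG-export layout).  Complex
#' signals come either as paired real/imaginary files or as a single file
#' of `a+bi` literals.
#'
#' @param path real-part (or complex-literal) file.
#' @param imag_path optional imaginary-part file of identical shape.
#' @param sep field separator (`","` for CSV, `"\t"` for TSV).
#' @param mode passed to [signal_ensemble()].
#' @return A [signal_ensemble()] (rows of the file become channels, i.e.
#'   columns of the ensemble).
#' @export
read_signals_csv <- function(path, imag_path = NULL, sep = ",",
                             mode = "timeseries") {
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character")
  M <- apply(as.matrix(raw), c(1, 2), function(s) as.complex(gsub(" ", "", s)))
  if (!is.null(imag_path)) {
    rawi <- utils::read.table(imag_path, sep = sep, header = FALSE)
    M <- M + 1i * as.matrix(rawi)
  }
  signal_ensemble(t(M), mode = mode)
}

#' Write an ensemble's signals as delimited text
#'
#' @param signals a [signal_ensemble()].
#' @param path output file (real parts, or complex literals if
#'   `imag_path` is `NULL` and the data are complex).
#' @param imag_path optional separate imaginary-part file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_signals_csv <- function(signals, path, imag_path = NULL, sep = ",") {
  stopifnot(inherits(signals, "ql_ensemble"))
  M <- t(signals$data)                  # channels x samples
  if (is.null(imag_path)) {
    txt <- apply(M, c(1, 2), function(z) {
      sprintf("%.17g%+.17gi", Re(z), Im(z))
    })
    utils::write.table(txt, path, sep = sep, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else {
    utils::write.table(Re(M), path, sep = sep, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(Im(M), imag_path, sep = sep, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Analysis configuration for the compound-network pipeline
#'
#' Validates and normalizes the configuration driving [run_pipeline()]:
#' where the two regions' signals come from (files or in-memory
#' ensembles), how channels group into regions, the bipartition, and which
#' side analyses to run.
#'
#' @param e1,e2 [signal_ensemble()]s for regions 1 and 2, or `NULL` if
#'   `input` files are given.
#' @param input optional list with `path`/`imag_path`/`sep` understood by
#'   [read_signals_csv()]; combined with `region1`/`region2` channel
#'   indices.
#' @param region1,region2 disjoint channel index vectors (file input only).
#' @param dims bipartition `c(N1, N2)`; defaults to the region sizes.
#' @param compound how the compound ensemble arises: `"product"` (build
#'   `Z_ij = z1_i z2_j` from the two regions) or `"direct"` (e1 already is
#'   the compound ensemble; e2/region2 unused).
#' @param center center signals before covariance estimation.
#' @param fc_metric optional functional-connectivity metric name (see
#'   [fc_matrix()]) computed on the raw region signals.
#' @param fs sampling frequency for spectral FC metrics.
#' @param seed integer seed recorded in the report (the pipeline itself is
#'   deterministic given the data).
#' @return A validated `ql_config` list.
#' @export
pipeline_config <- function(e1 = NULL, e2 = NULL, input = NULL,
                            region1 = NULL, region2 = NULL, dims = NULL,
                            compound = c("product", "direct"),
                            center = TRUE, fc_metric = NULL, fs = NULL,
                            seed = 1L) {
  compound <- match.arg(compound)
  if (is.null(e1) && is.null(input)) {
    stop("config error: supply either ensembles (e1[, e2]) or an input file spec")
  }
  if (!is.null(input)) {
    if (is.null(region1)) stop("config error: file input needs region1 indices")
    if (compound == "product" && is.null(region2)) {
      stop("config error: product pipeline needs region2 indices")
    }
    if (length(intersect(region1, region2)) > 0) {
      stop("config error: region channel sets must be disjoint")
    }
  }
  if (compound == "product" && is.null(input) && is.null(e2)) {
    stop("config error: product pipeline needs both ensembles")
  }
  structure(list(e1 = e1, e2 = e2, input = input,
                 region1 = region1, region2 = region2, dims = dims,
                 compound = compound, center = center,
                 fc_metric = fc_metric, fs = fs, seed = as.integer(seed)),
            class = "ql_config")
}

#' Run the compound-network entanglement pipeline
#'
#' End to end: load or take the region signals, center them, build the
#' compound ensemble, estimate its covariance, trace-normalize to a QL
#' state, and quantify entanglement; optionally attach a classical
#' functional-connectivity matrix for side-by-side comparison.  The output
#' is a pure function of (data, config): repeated runs are identical.
#'
#' @param config a [pipeline_config()].
#' @param out optional path; the report is additionally written as JSON.
#' @return A `ql_report` list: `config_digest`, `dims`, `covariance`
#'   (`ql_cov`), `state` (`ql_density`), `entanglement`
#'   ([entanglement_report()]), optional `fc`, and `provenance`.
#' @export
run_pipeline <- function(config, out = NULL) {
  stopifnot(inherits(config, "ql_config"))
  e1 <- config$e1; e2 <- config$e2
  if (!is.null(config$input)) {
    all_sig <- do.call(read_signals_csv, config$input)
    e1 <- signal_ensemble(all_sig$data[, config$region1, drop = FALSE],
                          mode = all_sig$mode)
    if (!is.null(config$region2)) {
      e2 <- signal_ensemble(all_sig$data[, config$region2, drop = FALSE],
                            mode = all_sig$mode)
    }
  }
  if (config$center) {
    e1 <- center_ensemble(e1)
    if (!is.null(e2)) e2 <- center_ensemble(e2)
  }
  if (config$compound == "product") {
    compound <- compound_ensemble(e1, e2)
    dims <- if (is.null(config$dims)) {
      c(e1$n_channels, e2$n_channels)
    } else config$dims
  } else {
    compound <- e1
    dims <- config$dims
    if (is.null(dims)) stop("config error: direct compound input needs dims")
  }
  C <- estimate_covariance(compound, center = config$center)
  rho <- normalize_to_density(C, dims = dims)
  ent <- entanglement_report(rho, dims)
  fc <- NULL
  if (!is.null(config$fc_metric)) {
    sig <- t(Re(cbind(e1$data, if (!is.null(e2)) e2$data)))
    fc <- fc_matrix(sig, metric = config$fc_metric, fs = config$fs)
  }
  report <- structure(list(
    dims = dims,
    covariance = C,
    state = rho,
    entanglement = ent,
    fc = fc,
    provenance = list(
      seed = config$seed,
      n_samples = compound$n,
      centered = config$center,
      compound = config$compound,
      index_order = "row-major k = (i-1)*N2 + j",
      log_base = 2,
      covariance_divisor = "n",
      package_version = as.character(utils::packageVersion("qlnet"))
    )
  ), class = "ql_report")
  if (!is.null(out)) write_report_json(report, out)
  report
}

#' @export
print.ql_report <- function(x, ...) {
  cat(sprintf("<ql_report> compound %s pipeline, n = %d samples\n",
              x$provenance$compound, x$provenance$n_samples))
  print(x$entanglement)
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' Scalars go out as bare numbers; matrices as `[re, im]` nested lists.
#'
#' @param report a `ql_report` from [run_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  ent <- report$entanglement
  payload <- list(
    dims = as.integer(report$dims),
    entanglement = list(
      negativity = ent$negativity,
      log_negativity = ent$log_negativity,
      concurrence = ent$concurrence,
      entanglement_entropy = ent$entanglement_entropy,
      S = ent$S, S_A = ent$S_A, S_B = ent$S_B,
      mutual_information = ent$mutual_information,
      purity = ent$purity,
      ppt_verdict = ent$ppt_verdict,
      schmidt_coefficients = ent$schmidt_coefficients
    ),
    covariance = matrix_to_reim(report$covariance$matrix),
    state = matrix_to_reim(report$state$matrix),
    fc = if (!is.null(report$fc)) report$fc,
    provenance = report$provenance
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a Hamiltonian spec from YAML
#'
#' The YAML holds `R` and `T` as nested lists of rows.
#'
#' @param path YAML file.
#' @return A [hamiltonian_spec()].
#' @export
read_hamiltonian_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$R) || is.null(y$T)) stop("spec YAML must contain R and T")
  hamiltonian_spec(do.call(rbind, y$R), do.call(rbind, y$T))
}

#' Write a Hamiltonian spec to YAML
#'
#' @param spec a [hamiltonian_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hamiltonian_yaml <- function(spec, path) {
  yaml::write_yaml(list(
    R = lapply(seq_len(nrow(spec$R)), function(i) as.numeric(spec$R[i, ])),
    T = lapply(seq_len(nrow(spec$T)), function(i) as.numeric(spec$T[i, ]))
  ), path)
  invisible(path)
}
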