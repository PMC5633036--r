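# JSON encoding helpers: named vectors and matrices keep their names.
enc_vec <- function(x) list(names = names(x), values = unname(as.vector(x)))
dec_vec <- function(l) {
  v <- as.numeric(unlist(l$values))
  if (!is.null(l$names) && length(l$names)) names(v) <- unlist(l$names)
  v
}
enc_mat <- function(m) list(rownames = rownames(m), colnames = colnames(m),
                            values = unname(as.vector(m)), nrow = nrow(m), ncol = ncol(m))
dec_mat <- function(l) {
  matrix(as.numeric(unlist(l$values)), l$nrow, l$ncol,
         dimnames = list(unlist(l$rownames), unlist(l$colnames)))
}

enc_norm <- function(nm) {
  out <- list(method = nm$method,
              size_factors = enc_vec(nm$size_factors),
              lib_sizes = enc_vec(nm$lib_sizes),
              genes = nm$genes)
  if (nm$method == "deseq") out$gene_geo_means <- enc_vec(nm$gene_geo_means)
  if (nm$method == "tmm") {
    out$log2_tmm <- enc_vec(nm$log2_tmm)
    out$reference <- nm$reference
    out$ref_counts <- enc_vec(nm$ref_counts)
    out$ref_lib_size <- nm$ref_lib_size
    out$trim_m <- nm$trim_m
    out$trim_a <- nm$trim_a
  }
  out
}
dec_norm <- function(l) {
  out <- list(method = l$method,
              size_factors = dec_vec(l$size_factors),
              lib_sizes = dec_vec(l$lib_sizes),
              genes = unlist(l$genes))
  if (l$method == "deseq") out$gene_geo_means <- dec_vec(l$gene_geo_means)
  if (l$method == "tmm") {
    out$log2_tmm <- dec_vec(l$log2_tmm)
    out$reference <- l$reference
    out$ref_counts <- dec_vec(l$ref_counts)
    out$ref_lib_size <- l$ref_lib_size
    out$trim_m <- l$trim_m
    out$trim_a <- l$trim_a
  }
  structure(out, class = "norm_model")
}

enc_moments <- function(mom) {
  list(class_means = enc_mat(mom$class_means),
       overall_mean = enc_vec(mom$overall_mean),
       class_vars = enc_mat(mom$class_vars),
       pooled_vars = enc_vec(mom$pooled_vars),
       class_sizes = enc_vec(mom$class_sizes),
       priors = enc_vec(mom$priors),
       classes = mom$classes, n = mom$n)
}
dec_moments <- function(l) {
  structure(list(class_means = dec_mat(l$class_means),
                 overall_mean = dec_vec(l$overall_mean),
                 class_vars = dec_mat(l$class_vars),
                 pooled_vars = dec_vec(l$pooled_vars),
                 class_sizes = dec_vec(l$class_sizes),
                 priors = dec_vec(l$priors),
                 classes = unlist(l$classes), n = l$n),
            class = "weighted_moments")
}

#' Serialize a fitted classifier to a JSON model file
#'
#' Writes everything prediction needs - normalization model, voom trend
#' knots and library statistics, weighted moments, shrunken centroids and
#' surviving genes (voomNSC) or variance statistics (voomDLDA/voomDQDA) -
#' so that prediction runs never touch the training counts. Numbers are
#' written at full double precision.
#'
#' @param model a fitted `voomdda_model`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_voomdda_model <- function(model, path) {
  obj <- list(format = "voomdda-model", version = 1L,
              flavor = model$flavor,
              classes = model$classes,
              priors = enc_vec(model$priors),
              genes = model$genes,
              norm = enc_norm(model$norm),
              voom = list(trend_x = model$voom$trend$x,
                          trend_y = model$voom$trend$y,
                          span = model$voom$trend$span,
                          lib_sizes = enc_vec(model$voom$lib_sizes),
                          geo_mean_lib = model$voom$geo_mean_lib),
              moments = enc_moments(model$moments))
  if (model$flavor == "voomNSC") {
    obj <- c(obj, list(lambda = model$lambda, s0 = model$s0,
                       m_k = enc_vec(model$m_k), s_wg = enc_vec(model$s_wg),
                       d = enc_mat(model$d), d_shrunk = enc_mat(model$d_shrunk),
                       shrunk_centroids = enc_mat(model$shrunk_centroids),
                       survivors = model$survivors))
  } else {
    obj$var_floor <- model$var_floor
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null")
  invisible(path)
}

#' Read a classifier model file written by [write_voomdda_model()]
#'
#' @param path path to the JSON model file
#' @return a `voomdda_model` usable with [predict.voomdda_model()]
#' @export
read_voomdda_model <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (!identical(l$format, "voomdda-model")) stop("not a voomdda model file")
  voom <- list(trend = structure(list(x = as.numeric(unlist(l$voom$trend_x)),
                                      y = as.numeric(unlist(l$voom$trend_y)),
                                      span = l$voom$span), class = "voom_trend"),
               lib_sizes = dec_vec(l$voom$lib_sizes),
               geo_mean_lib = l$voom$geo_mean_lib,
               genes = unlist(l$genes))
  model <- list(flavor = l$flavor, classes = unlist(l$classes),
                priors = dec_vec(l$priors), genes = unlist(l$genes),
                norm = dec_norm(l$norm), voom = voom,
                moments = dec_moments(l$moments))
  if (l$flavor == "voomNSC") {
    model <- c(model, list(lambda = l$lambda, s0 = l$s0,
                           m_k = dec_vec(l$m_k), s_wg = dec_vec(l$s_wg),
                           d = dec_mat(l$d), d_shrunk = dec_mat(l$d_shrunk),
                           shrunk_centroids = dec_mat(l$shrunk_centroids),
                           survivors = unlist(l$survivors)))
    class(model) <- c("voom_nsc_model", "voomdda_model")
  } else {
    model$var_floor <- l$var_floor
    class(model) <- c("voom_dda_model", "voomdda_model")
  }
  model
}
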