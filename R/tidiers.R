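#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PERMANOVA fit
#' @param x a [permanova()] result.
#' @param ... unused.
#' @return one-row tibble with the pseudo-F partition and p-value.
#' @method tidy permanova_fit
#' @export
tidy.permanova_fit <- function(x, ...) {
  tibble::tibble(term = c("among", "within"),
                 df = c(x$df_among, x$df_within),
                 sum_sq = c(x$ss_among, x$ss_within),
                 pseudo_f = c(x$pseudo_f, NA_real_),
                 p_value = c(x$p_value, NA_real_))
}

#' @rdname tidy.permanova_fit
#' @method glance permanova_fit
#' @export
glance.permanova_fit <- function(x, ...) {
  tibble::tibble(pseudo_f = x$pseudo_f, p_value = x$p_value,
                 df_among = x$df_among, df_within = x$df_within,
                 n_perm = x$n_perm)
}

#' Tidy a CAG partition
#' @param x a [cluster_cags()] result.
#' @param ... unused.
#' @return the feature-to-CAG assignment, joined with validation statistics
#'   when [validate_cags_permanova()] has run.
#' @method tidy cag_partition
#' @export
tidy.cag_partition <- function(x, ...) {
  out <- x$assignment
  if (!is.null(x$validation)) out <- dplyr::left_join(out, x$validation, by = "cag")
  out
}

#' @rdname tidy.cag_partition
#' @method glance cag_partition
#' @export
glance.cag_partition <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$assignment), n_cags = x$k,
    threshold = x$threshold, network_method = x$network_method,
    n_accepted = if (is.null(x$validation)) NA_integer_ else
      sum(x$validation$accepted, na.rm = TRUE))
}

#' Glance at a two-part association scan
#' @param x a [two_part_scan()] result.
#' @param ... unused.
#' @return one-row tibble: feature counts, significant counts at q < 0.05,
#'   and the split of winning components.
#' @method glance two_part_scan
#' @export
glance.two_part_scan <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_testable = sum(x$testable),
    n_q05 = sum(x$q_bh < 0.05, na.rm = TRUE),
    n_binary_wins = sum(x$winning_component == "binary", na.rm = TRUE),
    n_quant_wins = sum(x$winning_component == "quantitative", na.rm = TRUE),
    n_meta_wins = sum(x$winning_component == "meta", na.rm = TRUE))
}

#' Glance at a random-forest biomarker fit
#' @param x an [rf_biomarkers()] result.
#' @param ... unused.
#' @method glance rf_biomarkers
#' @export
glance.rf_biomarkers <- function(x, ...) {
  tibble::tibble(auc = x$auc, positive_class = x$positive_class,
                 n_biomarkers = nrow(x$ranking))
}

#' Tidy a metabolite module set
#' @param x a [metabolite_modules()] result.
#' @param ... unused.
#' @method tidy module_set
#' @export
tidy.module_set <- function(x, ...) x$assignment

#' @rdname tidy.module_set
#' @method glance module_set
#' @export
glance.module_set <- function(x, ...) {
  tibble::tibble(beta = x$beta,
                 n_modules = length(x$var_explained),
                 n_grey = sum(x$assignment$module == "grey"),
                 mean_var_explained = mean(x$var_explained))
}
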