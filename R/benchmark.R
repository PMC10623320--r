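# Access to the shipped benchmark tables: observed dominant indels, model
# top-5 predictions, and cut-site contexts for the nine sgRNAs of a
# published common-bean hairy-root RFO-gene editing study (see the TSV
# header comments under extdata/ for column semantics).

rfo_file <- function(name) {
  system.file("extdata", name, package = "rootindel", mustWork = TRUE)
}

#' Benchmark tables from a common-bean hairy-root editing study
#'
#' @return `rfo_observed_dominant()`: named list (`"PvSS sgRNA3"` etc.) of
#'   observed dominant indel sizes, pooled across the two Cas9 constructs in
#'   printed order. `rfo_predicted_lists()`: named list of per-model top-5
#'   predicted size lists. `rfo_cut_contexts()`: data.frame of cut-site
#'   contexts, microhomology-strength calls and observed 1-bp insertion base
#'   fractions.
#' @export
rfo_observed_dominant <- function() {
  d <- utils::read.delim(rfo_file("rfo_observed_indels.tsv"),
                         comment.char = "#")
  d$id <- paste(d$target, d$guide)
  lapply(split(d, d$id), function(x)
    unique(x$size[order(x$construct, x$rank)]))
}

#' @rdname rfo_observed_dominant
#' @export
rfo_predicted_lists <- function() {
  d <- utils::read.delim(rfo_file("rfo_predicted_indels.tsv"),
                         comment.char = "#")
  d$id <- paste(d$target, d$guide)
  lapply(split(d, d$id), function(x)
    lapply(split(x, x$model), function(m) m$size[order(m$rank)]))
}

#' @rdname rfo_observed_dominant
#' @export
rfo_cut_contexts <- function() {
  utils::read.delim(rfo_file("rfo_cut_contexts.tsv"), comment.char = "#",
                    stringsAsFactors = FALSE)
}
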