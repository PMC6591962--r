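#' Read and write pipeline tables
#'
#' Plain-text interchange for every pipeline artifact: molecule tables and
#' sample metadata as headered TSV, MePM matrices as wide TSV keyed by
#' `site_id:cpg_index`, site definitions as BED6+1 (column 7 holds the
#' comma-separated downstream CpG offsets), and marker sets as BED6+2
#' (name = `site_id:cpg_index`, score = tau x 1000, extra columns: source
#' tissue and selection status).
#'
#' @param x Object to write (see Details of each function).
#' @param path File path.
#' @name cfdecon-io
NULL

#' @rdname cfdecon-io
#' @export
write_molecules_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname cfdecon-io
#' @export
read_molecules_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", site_id = "c", molecule_id = "c", meth_states = "c"
  ))
}

#' @rdname cfdecon-io
#' @export
write_meta_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname cfdecon-io
#' @export
read_meta_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", group = "c", total_mapped_reads = "i",
    duplication_rate = "d", cfdna_ng_per_ml = "d"
  ))
}

#' @rdname cfdecon-io
#' @export
write_mepm_tsv <- function(x, path) {
  wide <- x |>
    select("marker_id", "sample_id", "mepm") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "mepm")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname cfdecon-io
#' @export
read_mepm_tsv <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(marker_id = "c",
                                                        .default = "d"))
  long <- tidyr::pivot_longer(wide, -"marker_id", names_to = "sample_id",
                              values_to = "mepm")
  parts <- stringr::str_split_fixed(long$marker_id, stringr::fixed(":"), 2)
  long$site_id <- parts[, 1]
  long$cpg_index <- as.integer(parts[, 2])
  long[, c("site_id", "cpg_index", "marker_id", "sample_id", "mepm")]
}

#' @rdname cfdecon-io
#' @export
write_sites_bed <- function(x, path) {
  bed <- tibble(
    chrom = x$chrom, start = x$start, end = x$end,
    name = x$site_id, score = 0L, strand = x$strand,
    cpg_offsets = vapply(x$cpg_offsets, paste, character(1), collapse = ",")
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname cfdecon-io
#' @export
read_sites_bed <- function(path) {
  bed <- readr::read_tsv(
    path, col_names = c("chrom", "start", "end", "name", "score", "strand",
                        "cpg_offsets"),
    col_types = "ciicicc"
  )
  tibble(
    site_id = bed$name, chrom = bed$chrom, start = bed$start, end = bed$end,
    strand = bed$strand,
    n_cpgs = lengths(strsplit(bed$cpg_offsets, ",")),
    cpg_offsets = lapply(strsplit(bed$cpg_offsets, ","), as.integer)
  )
}

#' @rdname cfdecon-io
#' @param marker_info Tibble with `marker_id`, `chrom`, `cpg_pos` used to
#'   locate each marker CpG.
#' @export
write_marker_set_bed <- function(x, marker_info, path) {
  sel <- x |>
    left_join(marker_info[, c("marker_id", "chrom", "cpg_pos")],
              by = "marker_id")
  bed <- tibble(
    chrom = sel$chrom, start = sel$cpg_pos, end = sel$cpg_pos + 2L,
    name = sel$marker_id,
    score = as.integer(round(pmin(pmax(sel$tau, 0), 1) * 1000)),
    strand = "+", source_tissue = sel$source_tissue, selected = sel$selected
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname cfdecon-io
#' @export
write_dm_tsv <- function(x, path) {
  readr::write_tsv(
    mutate(as_tibble(x), neg_log10_q = -log10(pmax(.data$q_value, 1e-300))),
    path
  )
  invisible(path)
}
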