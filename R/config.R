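# Pipeline configuration: one auditable list holding every processing
# constant and the simulator's study conditions. The packaged defaults
# live in inst/extdata/default_config.yaml.

#' Path to the packaged default configuration
#' @return Path to the YAML file shipped with the package.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "slclip",
              mustWork = TRUE)
}

#' Load the packaged default pipeline configuration
#'
#' The configuration is a named list with sections `genome`, `iclip`,
#' `thresholds` and `fp`, plus a top-level `seed`. Every published
#' processing constant (Phred cutoff, barcode layout, length filter,
#' locus cap, bin counts, FDR) and every simulator parameter (crosslink
#' offset, spacer range, Hill-model truth) is stored here rather than in
#' code.
#'
#' @return A nested named list.
#' @export
default_sim_config <- function() {
  yaml::read_yaml(default_config_path())
}

# recursive modifyList that rejects unknown keys so typos fail loudly;
# the sample tables (barcodes, roles) are replaced wholesale, since
# overriding them redefines the library layout rather than one entry
merge_config <- function(base, override, path = "") {
  for (i in seq_along(override)) {        # by position: repeated section
    nm <- names(override)[i]              # names apply sequentially
    ov <- override[[i]]
    if (is.null(nm) || !nm %in% names(base)) {
      abort(sprintf("unknown configuration key '%s%s'", path, nm %||% "?"))
    }
    if (nm %in% c("barcodes", "roles")) {
      base[[nm]] <- ov
    } else if (is.list(base[[nm]]) && is.list(ov) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], ov, paste0(path, nm, "$"))
    } else {
      base[[nm]] <- ov
    }
  }
  base
}

#' Build a pipeline configuration
#'
#' Starts from [default_sim_config()] (or `file`) and applies overrides
#' given as named sections, e.g.
#' `slclip_config(seed = 7, iclip = list(n_reads = 2000))`.
#' Unknown keys are rejected; the merged configuration is validated.
#'
#' @param ... Named overrides per section (`seed`, `genome`, `iclip`,
#'   `thresholds`, `fp`).
#' @param file Optional YAML file to use instead of the packaged default.
#' @return A validated configuration list.
#' @export
slclip_config <- function(..., file = NULL) {
  base <- if (is.null(file)) default_sim_config() else yaml::read_yaml(file)
  cfg <- merge_config(base, list(...))
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks the structural invariants: fractions in \[0, 1\], a
#' non-negative crosslink offset, the spacer range within the histone
#' spacer bounds, unique 6-nt barcodes, strictly increasing positive FP
#' concentrations and positive Kd.
#'
#' @param cfg A configuration list.
#' @return `cfg`, invisibly; aborts on an invalid configuration.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  need <- c("seed", "genome", "iclip", "thresholds", "fp")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0) {
    abort(paste0("configuration is missing section(s): ",
                 paste(missing, collapse = ", ")))
  }
  ic <- cfg$iclip
  fracs <- c(signal_fraction = ic$signal_fraction,
             mature_fraction = ic$mature_fraction,
             duplicate_rate = ic$duplicate_rate,
             control_depth_factor = ic$control_depth_factor,
             low_qual_rate = ic$low_qual_rate,
             offset_jitter_prob = ic$offset_jitter_prob)
  if (any(fracs < 0 | fracs > 1)) {
    abort("all iclip fractions/rates must lie in [0, 1]")
  }
  if (ic$crosslink_offset < 0) abort("crosslink_offset must be >= 0")
  sp <- cfg$genome$spacer_range
  if (length(sp) != 2 || sp[1] > sp[2] || sp[1] < 1) {
    abort("genome$spacer_range must be an increasing positive pair")
  }
  bc <- unlist(ic$barcodes)
  if (anyDuplicated(bc) > 0) abort("sample barcodes must be unique")
  if (any(nchar(bc) != ic$barcode_len)) {
    abort(sprintf("all barcodes must be %d nt", ic$barcode_len))
  }
  if (!all(names(ic$barcodes) %in% names(ic$roles))) {
    abort("every barcoded sample needs a role (IP or control)")
  }
  if (!all(unlist(ic$roles) %in% c("IP", "control"))) {
    abort("roles must be 'IP' or 'control'")
  }
  if (ic$umi1_len + ic$barcode_len + ic$umi2_len >= ic$read_len) {
    abort("read header (UMI1 + barcode + UMI2) must be shorter than read_len")
  }
  fp <- cfg$fp
  if (fp$kd_nm <= 0) abort("fp$kd_nm must be > 0")
  if (fp$conc_min_nm <= 0 || fp$conc_max_nm <= fp$conc_min_nm) {
    abort("fp concentration range must be positive and increasing")
  }
  th <- cfg$thresholds
  stopifnot(th$phred_min >= 0, th$min_len >= 1, th$min_overlap >= 1,
            th$max_loci >= 1, th$min_trim >= 0, th$flank >= 1,
            th$cds_bins >= 1, th$spacer_bins >= 1,
            th$fdr > 0, th$fdr < 1)
  invisible(cfg)
}

# header length in nt implied by the read layout
header_len <- function(cfg) {
  ic <- cfg$iclip
  ic$umi1_len + ic$barcode_len + ic$umi2_len
}

# stable short hash of a configuration, embedded in reports
config_hash <- function(cfg) {
  substr(rlang::hash(cfg), 1, 12)
}
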