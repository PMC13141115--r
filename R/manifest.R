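#' Channel manifest
#'
#' The manifest is the per-plane bookkeeping that drives hyperstack assembly
#' and naming: one row per acquired channel with columns `cycle` (1-based),
#' `channel_name` (filter/detector label), `marker` (antigen), `fluorophore`,
#' `exposure_ms` (> 0) and `role`, one of `nuclear`, `marker`,
#' `autofluorescence`, `brightfield`. Every cycle must contain exactly one
#' `nuclear` row (the DAPI/Hoechst registration reference) and
#' `(cycle, channel_name)` must be unique.
#'
#' @param path Path to a CSV file with the six columns above.
#' @return A validated `data.frame` of channel records, ordered as on file.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("cycle,channel_name,marker,fluorophore,exposure_ms,role",
#'              "1,DAPI,DAPI,DAPI,30,nuclear",
#'              "1,A647,LYVE-1,A647,200,marker"), tf)
#' read_manifest(tf)
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(df)
}

manifest_roles <- c("nuclear", "marker", "autofluorescence", "brightfield")

#' @rdname read_manifest
#' @param records A data.frame of channel records to validate in place.
#' @export
validate_manifest <- function(records) {
  required <- c("cycle", "channel_name", "marker", "fluorophore",
                "exposure_ms", "role")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "))
  }
  records <- records[, required]
  problems <- character()
  if (any(records$cycle != floor(records$cycle)) || any(records$cycle < 1)) {
    problems <- c(problems, "cycle must be a positive integer")
  }
  if (any(!is.finite(records$exposure_ms)) || any(records$exposure_ms <= 0)) {
    problems <- c(problems, "exposure_ms must be > 0")
  }
  bad_role <- setdiff(unique(records$role), manifest_roles)
  if (length(bad_role)) {
    problems <- c(problems, paste0("unknown role(s): ",
                                   paste(bad_role, collapse = ", ")))
  }
  key <- paste(records$cycle, records$channel_name, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    problems <- c(problems, paste0("duplicate (cycle, channel_name): ",
                                   paste(gsub("\r", "/", dup), collapse = ", ")))
  }
  for (cy in sort(unique(records$cycle))) {
    n_nuc <- sum(records$role[records$cycle == cy] == "nuclear")
    if (n_nuc == 0) {
      problems <- c(problems, sprintf("cycle %d: no nuclear channel", cy))
    } else if (n_nuc > 1) {
      problems <- c(problems,
                    sprintf("cycle %d: %d nuclear channels (need exactly 1)",
                            cy, n_nuc))
    }
  }
  if (length(problems)) {
    stop("invalid manifest:\n  - ", paste(problems, collapse = "\n  - "))
  }
  records$cycle <- as.integer(records$cycle)
  rownames(records) <- NULL
  records
}

#' Write a channel manifest to CSV
#'
#' @param records Validated manifest data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  records <- validate_manifest(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# The manifest row holding a cycle's nuclear reference.
nuclear_row <- function(records, cycle) {
  i <- which(records$cycle == cycle & records$role == "nuclear")
  if (length(i) != 1) stop(sprintf("cycle %d: no nuclear channel", cycle))
  i
}
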