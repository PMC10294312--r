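# Shared constants; file sorts first so these exist before the engine's
# state-index table is built at load time.

#' @keywords internal
CANCERS <- c("breast", "ovarian")

#' @keywords internal
HISTORIES <- c("none", "pbm", "pbso", "both")

#' @keywords internal
STAGE_LABELS <- list(
  breast  = paste0("pT", 1:4),
  ovarian = paste0("FIGO_", c("I", "II", "III", "IV"))
)
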