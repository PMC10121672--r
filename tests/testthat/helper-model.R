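# Calibrated model contexts shared across tests; built once per run.
.ctx_cache <- new.env(parent = emptyenv())

model_ctx <- function(tendon = "typical", alt = FALSE) {
  key <- paste0(tendon, if (alt) "_alt" else "")
  if (is.null(.ctx_cache[[key]])) {
    arch <- if (alt) muscle_architecture_alt(tendon = tendon)
            else muscle_architecture(tendon = tendon)
    path <- calibrate_path_offset(arch)
    .ctx_cache[[key]] <- list(arch = arch, path = path)
  }
  .ctx_cache[[key]]
}

# Cached block runs reused by several test files.
block_ctx <- function(design = "fig4", alt = FALSE) {
  key <- paste0("block_", design, if (alt) "_alt" else "")
  if (is.null(.ctx_cache[[key]])) {
    arch <- if (alt) muscle_architecture_alt() else muscle_architecture()
    .ctx_cache[[key]] <- run_block(arch, design = design)
  }
  .ctx_cache[[key]]
}
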