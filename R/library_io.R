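# Fragment-library export: numbered PDB files plus a manifest table.

#' Write a spherical fragment library to disk
#'
#' One numbered PDB file per fragment plus a tab-separated manifest
#' recording centre, size, scattering sum, domain and (when available)
#' the expected LLG. Actual fragment sizes are recorded rather than
#' enforced, so domain-edge fragments remain auditable.
#'
#' @param model the parent `xmodel`
#' @param lib output of [generate_sphere_library()]
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return invisibly, the manifest data.frame
#' @export
write_fragment_library <- function(model, lib, dir, prefix = "frag") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(seq_along(lib), function(i) {
    f <- lib[[i]]
    fm <- fragment_model(model, f)
    fn <- sprintf("%s_%03d.pdb", prefix, i)
    write_structure(fm, file.path(dir, fn))
    data.frame(file = fn, n_res = f$n_res,
               center_x = f$center[1], center_y = f$center[2],
               center_z = f$center[3], center_res = f$center_res,
               scattering = f$scattering, domain = f$domain_id,
               ellg = if (is.null(f$ellg)) NA_real_ else f$ellg)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, paste0(prefix, "_manifest.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
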