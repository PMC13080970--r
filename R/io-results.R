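#' Write a result table to TSV or JSON
#'
#' Serialises any package result (a tibble, or an object with a `tidy()`
#' method) with a deterministic column order, numbers at 6 significant
#' digits, and a provenance block (content hash, seed, discard window and
#' any other key/value pairs supplied). Writing the same object twice
#' yields byte-identical files.
#'
#' @param results A data frame, or a result object with a `tidy()` method.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param provenance Named list recorded alongside the data (e.g. `seed`,
#'   `discard_ps`, `stride`); a content hash is added automatically.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json"),
                          provenance = list()) {
  if (!is.character(format) || !all(format %in% c("tsv", "json"))) {
    abort(paste0("unknown format '", paste(format, collapse = ","),
                 "': must be 'tsv' or 'json'"))
  }
  format <- arg_match(format)
  df <- if (is.data.frame(results)) results else tidy(results)
  df <- as.data.frame(df)[, sort_columns_first(names(df)), drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  provenance$content_hash <- rlang::hash(list(df, provenance[setdiff(names(provenance), "content_hash")]))

  if (format == "tsv") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    hdr <- vapply(names(provenance), function(k)
      paste0("# ", k, ": ", paste(format(provenance[[k]], digits = 15), collapse = " ")),
      character(1))
    writeLines(hdr, con)
    writeLines(paste(names(df), collapse = "\t"), con)
    body <- do.call(paste, c(lapply(df, function(col) {
      if (is.numeric(col)) format(col, digits = 6, trim = TRUE, scientific = FALSE)
      else as.character(col)
    }), sep = "\t"))
    writeLines(body, con)
  } else {
    jsonlite::write_json(list(provenance = provenance, data = df), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

# stable column order: identity columns first, then the rest alphabetically
sort_columns_first <- function(nms) {
  lead <- intersect(c("frame", "time", "pair", "chain_id", "residue_index",
                      "residue_name", "atom_name", "atom_index"), nms)
  c(lead, sort(setdiff(nms, lead)))
}
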