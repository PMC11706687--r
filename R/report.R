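# HTML analysis report: per-sample panels (brightfield, segmentation, ratio,
# uncertainty, attribution) plus the statistics tables, self-contained
# (images embedded as base64 data URIs; renders with zero network access).

b64img <- function(bytes) {
  sprintf('<img src="data:image/png;base64,%s" alt=""/>', jsonlite::base64_enc(bytes))
}

html_table <- function(df, digits = 4) {
  if (is.null(df) || nrow(df) == 0) return("<p><em>none</em></p>")
  fmt <- function(v) {
    if (is.numeric(v)) formatC(v, digits = digits, format = "g") else as.character(v)
  }
  head_row <- paste0("<tr>", paste0("<th>", names(df), "</th>", collapse = ""), "</tr>")
  rows <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(names(df), function(cn) fmt(df[[cn]][i]), character(1))
    paste0("<tr>", paste0("<td>", cells, "</td>", collapse = ""), "</tr>")
  }, character(1))
  paste0("<table>", head_row, paste(rows, collapse = ""), "</table>")
}

render_report <- function(path, sample_panels, measures, comparisons, manifest) {
  css <- "
  body { font-family: sans-serif; margin: 2em; max-width: 1100px; }
  table { border-collapse: collapse; margin: 1em 0; }
  th, td { border: 1px solid #999; padding: 3px 8px; font-size: 13px; }
  .panel { display: inline-block; margin: 4px; text-align: center;
           font-size: 12px; vertical-align: top; }
  .panel img { display: block; image-rendering: pixelated; width: 160px; }
  .sample { border-top: 1px solid #ccc; padding-top: 8px; }
  .note { color: #555; font-size: 13px; }"
  parts <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'/>",
    "<title>Root zone ratiometric analysis</title>",
    sprintf("<style>%s</style></head><body>", css),
    "<h1>Root developmental zone ratiometric analysis</h1>",
    sprintf("<p class='note'>rootzones %s | seed %s | %d samples analyzed, %d failed</p>",
            manifest$package_version, manifest$seed,
            sum(vapply(manifest$samples, function(s) identical(s$status, "ok"), logical(1))),
            sum(vapply(manifest$samples, function(s) !identical(s$status, "ok"), logical(1)))),
    "<h2>Group comparisons (Welch's t-test)</h2>",
    "<p class='note'>Raw two-sided p values; several zones and contrasts are tested without multiplicity correction.</p>",
    html_table(comparisons),
    "<h2>Per-sample zone mean 458/405 ratios</h2>",
    html_table(measures),
    "<h2>Per-sample panels</h2>")
  for (sp in sample_panels) {
    panel_html <- vapply(names(sp$panels), function(nm) {
      sprintf("<span class='panel'>%s<br/>%s</span>", b64img(sp$panels[[nm]]), nm)
    }, character(1))
    parts <- c(parts,
               sprintf("<div class='sample'><h3>%s <span class='note'>(%s, %s)</span></h3>%s</div>",
                       sp$sample_id, sp$line, sp$treatment,
                       paste(panel_html, collapse = "")))
  }
  parts <- c(parts, "</body></html>")
  writeLines(paste(parts, collapse = "\n"), path)
  invisible(path)
}
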