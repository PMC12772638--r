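# Fixed report palette and geometry, versioned so golden-file comparisons
# are stable. Bump the version when anything here changes.
.styleSheets <- list(
  "1.0" = list(
    intraFill = "#fdbf6f", extraFill = "#1f78b4", diamStroke = "#000000",
    red = "#d7191c", orange = "#fdae61", green = "#1a9641",
    panelPx = 170, chartW = 430, chartH = 170, pad = 34,
    css = paste(
      "body{font-family:Helvetica,Arial,sans-serif;margin:16px;color:#222;}",
      "h1{font-size:20px;} h2{font-size:15px;margin-bottom:4px;}",
      ".panels{display:flex;flex-wrap:wrap;gap:10px;}",
      ".panel{border:3px solid #ccc;padding:6px;font-size:12px;}",
      ".panel .val{font-weight:bold;}",
      ".charts{display:flex;gap:24px;flex-wrap:wrap;margin-top:10px;}",
      ".legend{border-top:1px solid #999;margin-top:14px;padding-top:6px;",
      "font-size:11px;color:#444;}",
      "table{border-collapse:collapse;font-size:12px;}",
      "td,th{border:1px solid #999;padding:3px 7px;text-align:right;}",
      "th{background:#eee;}",
      sep = "\n")
  )
)

.num <- function(x, digits = 2) {
  ifelse(is.na(x), "-", sprintf(paste0("%.", digits, "f"), x))
}

.decisionIcons <- c(surveillance = "&#128065;", SRS = "&#9889;",
                    surgery = "&#9986;", discharge = "&#10004;")

.iconFor <- function(label) {
  if (is.na(label) || !nzchar(label)) return("")
  ic <- .decisionIcons[label]
  if (is.na(ic)) label else unname(ic)
}

#' Build the render-ready report specification
#'
#' Assembles the deterministic content of a patient's summary report from the
#' measured and assessed timeline: per-session panels (axial mask snapshot at
#' the displayed-diameter slice with the diameter endpoints, diameter value,
#' volumes), the stacked volume bar chart, the diameter-vs-months line chart,
#' per-session colours mapped one-to-one from the consecutive growth
#' assessments (growth red, equivocal orange, no growth or reduction green;
#' the index session is green), decision icons and notes. Volume entries are
#' suppressed for sessions whose tumour occupies at most one axial slice
#' (toggle with `suppressSingleSlice`). This layer performs no measurement.
#'
#' @param timeline A [PatientTimeline-class].
#' @param measurements List of [SessionMeasurements-class] per session.
#' @param assessment Result of [assessTimeline()] on the same sessions.
#' @param volumes Optional list of [LabeledVolume-class] per session; when
#'   given, panels carry the axial label slice for the snapshot.
#' @param suppressSingleSlice Suppress volume display for tumours confined to
#'   a single axial slice (default TRUE).
#' @param styleVersion Report style sheet version (default "1.0").
#' @return A [ReportSpec-class].
#' @export
buildReportSpec <- function(timeline, measurements, assessment,
                            volumes = NULL, suppressSingleSlice = TRUE,
                            styleVersion = "1.0") {
  stopifnot(is(timeline, "PatientTimeline"))
  s <- timeline@sessions
  n <- nrow(s)
  stopifnot(length(measurements) == n)
  choices <- assessment$choices
  cons <- assessment$consecutive

  colors <- rep("green", n)
  if (n >= 2L) for (i in 2:n) {
    colors[i] <- switch(cons[[i - 1L]]@status,
                        growth = "red", equivocal = "orange", "green")
  }
  panels <- vector("list", n)
  suppressed <- logical(n)
  for (i in seq_len(n)) {
    m <- measurements[[i]]
    ch <- choices[[i]]
    diam <- if (ch@chosen == "DEM") m@diamExtra else m@diamWhole
    k <- diam@sliceIndex
    if (is.na(k)) k <- m@referenceSlice
    sliceMat <- NULL
    spacing <- c(1, 1)
    if (!is.null(volumes) && !is.na(k)) {
      sliceMat <- maskArray(volumes[[i]])[, , k]
      spacing <- voxelSpacing(volumes[[i]])[1:2]
    }
    suppressed[i] <- suppressSingleSlice && m@nAxialSlices <= 1L
    panels[[i]] <- list(
      session = i,
      date = format(s$session_date[i]),
      months = s$months_since_index[i],
      status = s$operative_status[i],
      sliceIndex = k,
      sliceMatrix = sliceMat,
      spacing = spacing,
      endpointA = diam@endpointA,
      endpointB = diam@endpointB,
      diameterType = ch@chosen,
      diameterValue = ch@value,
      branch = ch@branch,
      vIntra = m@vIntra, vExtra = m@vExtra, vWhole = m@vWhole,
      suppressed = suppressed[i]
    )
  }
  notes <- character()
  if (n < 2L)
    notes <- c(notes, "Single session: growth not assessable.")
  if (n >= 2L) {
    switched <- vapply(cons, function(a) a@basisSwitched, logical(1))
    if (any(switched))
      notes <- c(notes, sprintf(
        "Diameter basis switched between sessions %s; those deltas use the whole-tumour diameter for both sessions.",
        paste(which(switched) + 1L, collapse = ", ")))
  }
  if (any(suppressed))
    notes <- c(notes,
      "Volumes are not shown for tumours confined to a single axial slice.")
  new("ReportSpec",
      patientId = timeline@patientId,
      styleVersion = styleVersion,
      panels = panels,
      months = s$months_since_index,
      colors = colors,
      decisions = as.character(s$decision_label),
      barIntra = vapply(measurements, function(m) m@vIntra, numeric(1)),
      barExtra = vapply(measurements, function(m) m@vExtra, numeric(1)),
      lineValues = vapply(choices, function(ch) ch@value, numeric(1)),
      lineTypes = vapply(choices, function(ch) ch@chosen, character(1)),
      suppressed = suppressed,
      headline = list(indexVsLatest = assessment$indexVsLatest,
                      penultimateVsLatest = assessment$penultimateVsLatest),
      notes = notes)
}

# --- deterministic SVG emitters -------------------------------------------

.svgOpen <- function(w, h) {
  sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                 'height="%d" viewBox="0 0 %d %d">'),
          round(w), round(h), round(w), round(h))
}

# Axial mask snapshot: label runs as rects, diameter endpoints as a line.
.svgSlice <- function(panel, st) {
  mat <- panel$sliceMatrix
  if (is.null(mat))
    return(paste0(.svgOpen(st$panelPx, st$panelPx),
                  '<text x="10" y="20" font-size="11">no snapshot</text></svg>'))
  sp <- panel$spacing
  ext <- c(nrow(mat) * sp[1], ncol(mat) * sp[2])
  sc <- st$panelPx / max(ext)
  w <- ext[1] * sc; h <- ext[2] * sc
  px <- function(x) sprintf("%.2f", x)
  out <- c(.svgOpen(w, h),
           sprintf('<rect width="%s" height="%s" fill="#111111"/>', px(w), px(h)))
  # screen y runs down; flip the anatomical y axis
  for (j in seq_len(ncol(mat))) {
    r <- rle(mat[, j])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (q in seq_along(r$values)) {
      v <- r$values[q]
      if (v == 0L) next
      fill <- if (v == 1L) st$intraFill else st$extraFill
      out <- c(out, sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
        px((starts[q] - 1.5) * sp[1] * sc), px(h - (j - 0.5) * sp[2] * sc),
        px(r$lengths[q] * sp[1] * sc), px(sp[2] * sc), fill))
    }
  }
  ea <- panel$endpointA; eb <- panel$endpointB
  if (!anyNA(ea) && !anyNA(eb)) {
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1.5" stroke-dasharray="4,2"/>',
      px((ea[1] + 0.5 * sp[1]) * sc), px(h - (ea[2] + 0.5 * sp[2]) * sc),
      px((eb[1] + 0.5 * sp[1]) * sc), px(h - (eb[2] + 0.5 * sp[2]) * sc),
      st$diamStroke))
  }
  paste0(paste(out, collapse = ""), "</svg>")
}

# Stacked intra-/extrameatal volume bars, one group per session.
.svgBarChart <- function(spec, st) {
  n <- length(spec@panels)
  w <- st$chartW; h <- st$chartH; pad <- st$pad
  vmax <- max(spec@barIntra + spec@barExtra, 1e-9)
  px <- function(x) sprintf("%.2f", x)
  bw <- (w - 2 * pad) / max(n, 1) * 0.55
  out <- c(.svgOpen(w, h + 18),
           sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#333"/>',
                   px(pad), px(h - pad), px(w - 10), px(h - pad)),
           sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#333"/>',
                   px(pad), px(10), px(pad), px(h - pad)))
  for (tick in pretty(c(0, vmax), 3)) {
    if (tick < 0 || tick > vmax * 1.05) next
    y <- h - pad - (h - pad - 10) * tick / vmax
    out <- c(out,
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#bbb"/>',
              px(pad - 3), px(y), px(pad), px(y)),
      sprintf('<text x="%s" y="%s" font-size="9" text-anchor="end">%s</text>',
              px(pad - 5), px(y + 3), .num(tick, 1)))
  }
  for (i in seq_len(n)) {
    xc <- pad + (w - 2 * pad) * (i - 0.5) / n
    if (spec@suppressed[i]) {
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-size="9" text-anchor="middle">n/a</text>',
        px(xc), px(h - pad - 6)))
    } else {
      hi <- (h - pad - 10) * spec@barIntra[i] / vmax
      he <- (h - pad - 10) * spec@barExtra[i] / vmax
      out <- c(out, sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
        px(xc - bw / 2), px(h - pad - hi), px(bw), px(hi), st$intraFill),
        sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
        px(xc - bw / 2), px(h - pad - hi - he), px(bw), px(he), st$extraFill))
    }
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="9" text-anchor="middle">%s</text>',
      px(xc), px(h - pad + 12), spec@panels[[i]]$date))
  }
  out <- c(out, sprintf(
    '<text x="%s" y="%s" font-size="10" text-anchor="middle">Intra-/extrameatal volume (cm&#179;)</text>',
    px(w / 2), px(h + 12)))
  paste0(paste(out, collapse = ""), "</svg>")
}

# Displayed diameter against months since index, points coloured by the
# session-to-session change, decision icons above the points.
.svgLineChart <- function(spec, st) {
  n <- length(spec@panels)
  w <- st$chartW; h <- st$chartH; pad <- st$pad
  px <- function(x) sprintf("%.2f", x)
  mmax <- max(spec@months, 1e-9)
  dmax <- max(spec@lineValues, 1e-9)
  xAt <- function(mo) pad + (w - pad - 14) * mo / mmax
  yAt <- function(d) h - pad - (h - pad - 14) * d / dmax
  out <- c(.svgOpen(w, h + 18),
           sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#333"/>',
                   px(pad), px(h - pad), px(w - 10), px(h - pad)),
           sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#333"/>',
                   px(pad), px(10), px(pad), px(h - pad)))
  for (tick in pretty(c(0, dmax), 3)) {
    if (tick < 0 || tick > dmax * 1.05) next
    y <- yAt(tick)
    out <- c(out,
      sprintf('<text x="%s" y="%s" font-size="9" text-anchor="end">%s</text>',
              px(pad - 5), px(y + 3), .num(tick, 0)))
  }
  for (tick in pretty(c(0, mmax), 4)) {
    if (tick < 0 || tick > mmax * 1.02) next
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="9" text-anchor="middle">%s</text>',
      px(xAt(tick)), px(h - pad + 12), .num(tick, 0)))
  }
  if (n >= 2L) {
    pts <- paste(sprintf("%.2f,%.2f", xAt(spec@months), yAt(spec@lineValues)),
                 collapse = " ")
    out <- c(out, sprintf(
      '<polyline points="%s" fill="none" stroke="#777" stroke-width="1.2"/>', pts))
  }
  for (i in seq_len(n)) {
    col <- switch(spec@colors[i], red = st$red, orange = st$orange, st$green)
    out <- c(out, sprintf(
      '<circle cx="%s" cy="%s" r="4.5" fill="%s" stroke="#333"/>',
      px(xAt(spec@months[i])), px(yAt(spec@lineValues[i])), col))
    ic <- .iconFor(spec@decisions[i])
    if (nzchar(ic))
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-size="11" text-anchor="middle">%s</text>',
        px(xAt(spec@months[i])), px(yAt(spec@lineValues[i]) - 9), ic))
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="8" text-anchor="middle">%s</text>',
      px(xAt(spec@months[i])), px(yAt(spec@lineValues[i]) + 14),
      spec@lineTypes[i]))
  }
  out <- c(out, sprintf(
    '<text x="%s" y="%s" font-size="10" text-anchor="middle">Displayed maximum diameter (mm) vs months since index</text>',
    px(w / 2), px(h + 12)))
  paste0(paste(out, collapse = ""), "</svg>")
}

.legendHtml <- function(spec, st) {
  items <- c(
    sprintf('<span style="color:%s">&#9679;</span> growth', st$red),
    sprintf('<span style="color:%s">&#9679;</span> equivocal growth', st$orange),
    sprintf('<span style="color:%s">&#9679;</span> no growth / reduction', st$green),
    sprintf('<span style="color:%s">&#9632;</span> intrameatal', st$intraFill),
    sprintf('<span style="color:%s">&#9632;</span> extrameatal', st$extraFill),
    paste(vapply(names(.decisionIcons),
                 function(k) sprintf("%s %s", .decisionIcons[[k]], k),
                 character(1)), collapse = " &nbsp; ")
  )
  paste0('<div class="legend">Guide: ', paste(items, collapse = " &nbsp;|&nbsp; "),
         if (length(spec@notes))
           paste0("<br/>", paste(spec@notes, collapse = "<br/>")) else "",
         "</div>")
}

.headlineHtml <- function(spec) {
  fmtGA <- function(a, label) {
    if (a@status == "not_assessable")
      return(sprintf("<li>%s: not assessable</li>", label))
    sprintf("<li>%s: <b>%s</b> (&#916;D %s mm, &#916;V %s cm&#179;%s)%s</li>",
            label, gsub("_", " ", a@status), .num(a@deltaD),
            .num(a@deltaV, 3),
            if (is.na(a@deltaVPct)) "" else sprintf(", %s%%", .num(a@deltaVPct, 1)),
            if (length(a@triggeredBy))
              sprintf(" [criteria: %s]", paste(a@triggeredBy, collapse = ", "))
            else "")
  }
  paste0("<ul>",
         fmtGA(spec@headline$indexVsLatest, "Index vs most recent"),
         fmtGA(spec@headline$penultimateVsLatest,
               "Second most recent vs most recent"),
         "</ul>")
}

#' Render the summary report
#'
#' Writes a one-page-per-patient summary report: the session panels, volume
#' bar chart, diameter line chart, headline growth assessments and legend,
#' in the fixed versioned style. HTML output (inline SVG) is byte-stable for
#' identical inputs and style version; the PDF variant is drawn with base R
#' graphics and is not byte-stable (the PDF format embeds creation
#' timestamps).
#'
#' @param spec A [ReportSpec-class] from [buildReportSpec()].
#' @param out Output file path.
#' @param format "html" (canonical) or "pdf".
#' @return `out`, invisibly.
#' @export
renderSummaryReport <- function(spec, out, format = c("html", "pdf")) {
  stopifnot(is(spec, "ReportSpec"))
  format <- match.arg(format)
  st <- .styleSheets[[spec@styleVersion]]
  if (is.null(st))
    stop(sprintf("unknown style version '%s'", spec@styleVersion))
  if (format == "pdf") return(.renderSummaryPdf(spec, out, st))

  panelHtml <- vapply(seq_along(spec@panels), function(i) {
    p <- spec@panels[[i]]
    border <- switch(spec@colors[i], red = st$red, orange = st$orange, st$green)
    volTxt <- if (p$suppressed) "volumes n/a (single-slice tumour)"
      else sprintf(
        "V intra %s / extra %s / whole <span class=\"val\">%s</span> cm&#179;",
        .num(p$vIntra, 3), .num(p$vExtra, 3), .num(p$vWhole, 3))
    paste0(
      sprintf('<div class="panel" style="border-color:%s">', border),
      sprintf("<div><b>%s</b> &nbsp; %s &nbsp; %s mo</div>",
              p$date, p$status, .num(p$months, 1)),
      .svgSlice(p, st),
      sprintf('<div>%s = <span class="val">%s mm</span> (slice %s)</div>',
              p$diameterType, .num(p$diameterValue),
              ifelse(is.na(p$sliceIndex), "-", p$sliceIndex)),
      sprintf("<div>%s</div>", volTxt),
      "</div>")
  }, character(1))

  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    sprintf("<title>Imaging biomarker summary report - %s</title>",
            spec@patientId),
    sprintf("<!-- style version %s -->", spec@styleVersion),
    "<style>", st$css, "</style></head><body>",
    sprintf("<h1>Imaging biomarker summary report &mdash; patient %s</h1>",
            spec@patientId),
    "<h2>Sessions</h2>",
    '<div class="panels">', panelHtml, "</div>",
    "<h2>Longitudinal change</h2>",
    .headlineHtml(spec),
    '<div class="charts">',
    .svgBarChart(spec, st),
    .svgLineChart(spec, st),
    "</div>",
    .legendHtml(spec, st),
    "</body></html>")
  writeLines(html, out, useBytes = TRUE)
  invisible(out)
}

.renderSummaryPdf <- function(spec, out, st) {
  n <- length(spec@panels)
  grDevices::pdf(out, width = 10, height = 7)
  on.exit(grDevices::dev.off())
  graphics::layout(rbind(seq_len(max(n, 1)),
                         rep(max(n, 1) + 1L, max(n, 1)),
                         rep(max(n, 1) + 2L, max(n, 1))),
                   heights = c(1.3, 1, 1))
  for (i in seq_len(n)) {
    p <- spec@panels[[i]]
    graphics::par(mar = c(1, 1, 2, 1))
    if (!is.null(p$sliceMatrix)) {
      graphics::image(seq_len(nrow(p$sliceMatrix)) * p$spacing[1],
                      seq_len(ncol(p$sliceMatrix)) * p$spacing[2],
                      p$sliceMatrix, col = c("#111111", st$intraFill,
                                             st$extraFill),
                      zlim = c(0, 2), asp = 1, axes = FALSE, xlab = "",
                      ylab = "", main = p$date, cex.main = 0.9)
    } else {
      graphics::plot.new(); graphics::title(main = p$date, cex.main = 0.9)
    }
    graphics::mtext(sprintf("%s %.2f mm", p$diameterType, p$diameterValue),
                    side = 1, cex = 0.7)
  }
  graphics::par(mar = c(3, 4, 2, 1))
  graphics::barplot(rbind(spec@barIntra, spec@barExtra),
                    names.arg = vapply(spec@panels, `[[`, character(1), "date"),
                    col = c(st$intraFill, st$extraFill),
                    ylab = "volume (cm^3)", cex.names = 0.7, cex.axis = 0.7)
  cols <- vapply(spec@colors, function(cc)
    switch(cc, red = st$red, orange = st$orange, st$green), character(1))
  graphics::plot(spec@months, spec@lineValues, type = "o", pch = 21,
                 bg = cols, xlab = "months since index",
                 ylab = "diameter (mm)", cex = 1.3)
  invisible(out)
}

# --- extended report -------------------------------------------------------

# Flat per-session measurement table (also the cmdMeasure CSV schema).
.measurementsFrame <- function(timeline, measurements, choices) {
  s <- timeline@sessions
  n <- nrow(s)
  do.call(rbind, lapply(seq_len(n), function(i) {
    m <- measurements[[i]]
    ch <- choices[[i]]
    data.frame(
      patient_id = timeline@patientId,
      session = i,
      session_date = format(s$session_date[i]),
      months_since_index = s$months_since_index[i],
      operative_status = s$operative_status[i],
      d_wt_mm = m@dWT, d_em_mm = m@dEM,
      d_intra_par_mm = m@dIntraPar, d_extra_par_mm = m@dExtraPar,
      d_extra_perp_mm = m@dExtraPerp,
      v_intra_cm3 = m@vIntra, v_extra_cm3 = m@vExtra,
      v_whole_cm3 = m@vWhole,
      n_axial_slices = m@nAxialSlices,
      reference_slice = m@referenceSlice,
      entirely_intrameatal = m@entirelyIntrameatal,
      display_diameter = ch@chosen,
      display_value_mm = ch@value,
      selection_branch = ch@branch,
      decision_label = as.character(s$decision_label[i]),
      stringsAsFactors = FALSE)
  }))
}

# Orthographic silhouette of the mask along one array axis, as SVG.
.svgProjection <- function(vol, axis, st, side = 120) {
  a <- maskArray(vol) > 0L
  proj <- apply(a, setdiff(1:3, axis), any)
  sp <- voxelSpacing(vol)[setdiff(1:3, axis)]
  ext <- dim(proj) * sp
  sc <- side / max(ext, 1e-9)
  px <- function(x) sprintf("%.2f", x)
  w <- ext[1] * sc; h <- ext[2] * sc
  out <- c(.svgOpen(w, h),
           sprintf('<rect width="%s" height="%s" fill="#111111"/>', px(w), px(h)))
  for (j in seq_len(ncol(proj))) {
    r <- rle(proj[, j])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (q in seq_along(r$values)) {
      if (!r$values[q]) next
      out <- c(out, sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="#cccccc"/>',
        px((starts[q] - 1.5) * sp[1] * sc), px(h - (j - 0.5) * sp[2] * sc),
        px(r$lengths[q] * sp[1] * sc), px(sp[2] * sc)))
    }
  }
  paste0(paste(out, collapse = ""), "</svg>")
}

# ASCII STL of the voxel surface: one quad (two triangles) per exposed voxel
# face, outward winding. The mesh is closed by construction and its signed
# volume equals the voxel-count volume.
.writeStl <- function(vol, path, name = "tumour") {
  a <- maskArray(vol) > 0L
  sp <- voxelSpacing(vol)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  # face directions: axis, sign, outward normal
  dirs <- list(c(1, 1), c(1, -1), c(2, 1), c(2, -1), c(3, 1), c(3, -1))
  for (d in dirs) {
    axis <- d[1]; sgn <- d[2]
    exposed <- a & !.shift3(a, axis, -sgn)
    idx <- which(exposed)
    if (!length(idx)) next
    ai <- arrayInd(idx, dim(a))
    ctr <- sweep(ai - 1, 2, sp, "*")
    half <- sp / 2
    # quad corners in the face plane, wound counter-clockwise seen from
    # outside (normal = sgn * axis)
    o1 <- setdiff(1:3, axis)[1]; o2 <- setdiff(1:3, axis)[2]
    corner <- function(s1, s2) {
      v <- ctr
      v[, axis] <- v[, axis] + sgn * half[axis]
      v[, o1] <- v[, o1] + s1 * half[o1]
      v[, o2] <- v[, o2] + s2 * half[o2]
      v
    }
    # CCW in the (o1, o2) plane yields normal +axis for axes 1 and 3 but
    # -axis for axis 2 (odd permutation); flip accordingly
    cs <- if ((axis != 2) == (sgn > 0))
      list(corner(-1, -1), corner(1, -1), corner(1, 1), corner(-1, 1))
    else
      list(corner(-1, -1), corner(-1, 1), corner(1, 1), corner(1, -1))
    nrm <- c(0, 0, 0); nrm[axis] <- sgn
    emit <- function(v1, v2, v3) {
      lines <- sprintf(
        "facet normal %d %d %d\nouter loop\nvertex %.6f %.6f %.6f\nvertex %.6f %.6f %.6f\nvertex %.6f %.6f %.6f\nendloop\nendfacet",
        nrm[1], nrm[2], nrm[3],
        v1[, 1], v1[, 2], v1[, 3], v2[, 1], v2[, 2], v2[, 3],
        v3[, 1], v3[, 2], v3[, 3])
      writeLines(lines, con)
    }
    emit(cs[[1]], cs[[2]], cs[[3]])
    emit(cs[[1]], cs[[3]], cs[[4]])
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Render the extended report
#'
#' Writes the extended per-patient document: the full per-session measurement
#' table (every measured field for every session), three orthographic
#' silhouette projections per session, and one STL surface mesh per session
#' (written next to `out` as `<basename>_sNN.stl`).
#'
#' @param timeline A [PatientTimeline-class].
#' @param measurements List of [SessionMeasurements-class] per session.
#' @param out Output HTML path.
#' @param volumes Optional list of [LabeledVolume-class] per session; needed
#'   for projections and meshes.
#' @param assessment Optional [assessTimeline()] result; computed display
#'   choices default to DWT when omitted.
#' @param styleVersion Report style sheet version.
#' @return `out`, invisibly.
#' @export
renderExtendedReport <- function(timeline, measurements, out, volumes = NULL,
                                 assessment = NULL, styleVersion = "1.0") {
  stopifnot(is(timeline, "PatientTimeline"))
  st <- .styleSheets[[styleVersion]]
  if (is.null(st)) stop(sprintf("unknown style version '%s'", styleVersion))
  choices <- if (!is.null(assessment)) assessment$choices
    else lapply(measurements, function(m)
      new("DiameterChoice", chosen = "DWT", value = m@dWT,
          branch = "postoperative", axisAvailable = TRUE))
  tab <- .measurementsFrame(timeline, measurements, choices)

  fmtCell <- function(x) {
    if (is.numeric(x)) .num(x, 3) else ifelse(is.na(x), "-", as.character(x))
  }
  header <- paste0("<tr>", paste0("<th>", names(tab), "</th>", collapse = ""),
                   "</tr>")
  body <- vapply(seq_len(nrow(tab)), function(i) {
    paste0("<tr>", paste0("<td>",
                          vapply(tab[i, ], fmtCell, character(1)),
                          "</td>", collapse = ""), "</tr>")
  }, character(1))

  meshHtml <- character()
  if (!is.null(volumes)) {
    base <- sub("\\.html?$", "", out)
    meshHtml <- vapply(seq_along(volumes), function(i) {
      stl <- sprintf("%s_s%02d.stl", base, i)
      if (sum(maskArray(volumes[[i]]) > 0L) > 0L) .writeStl(volumes[[i]], stl)
      projs <- paste(vapply(1:3, function(ax)
        .svgProjection(volumes[[i]], ax, st), character(1)), collapse = " ")
      sprintf('<div class="panel"><div><b>Session %d</b> (mesh: %s)</div>%s</div>',
              i, basename(stl), projs)
    }, character(1))
  }

  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    sprintf("<title>Extended imaging biomarker report - %s</title>",
            timeline@patientId),
    sprintf("<!-- style version %s -->", styleVersion),
    "<style>", st$css, "</style></head><body>",
    sprintf("<h1>Extended imaging biomarker report &mdash; patient %s</h1>",
            timeline@patientId),
    "<h2>All measurements</h2>",
    "<table>", header, body, "</table>",
    if (length(meshHtml)) c("<h2>3D visualization (orthographic silhouettes)</h2>",
                            '<div class="panels">', meshHtml, "</div>") else NULL,
    "</body></html>")
  writeLines(html, out, useBytes = TRUE)
  invisible(out)
}
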