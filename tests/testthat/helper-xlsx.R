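## Builds a small synthetic workbook with python/openpyxl so the
## package's pure-R workbook reader can be checked against an
## independently produced .xlsx file. Sheets are passed as a list of
## data.frames; everything is written as strings or numbers.

writeXlsxFixture <- function(sheets, path) {
  payload <- lapply(sheets, function(df) {
    lapply(seq_len(nrow(df)), function(i)
      unname(as.list(df[i, , drop = TRUE])))
  })
  spec <- list(path = path,
               sheets = lapply(names(sheets), function(nm)
                 list(name = nm,
                      header = as.list(names(sheets[[nm]])),
                      rows = payload[[nm]])))
  spec_path <- tempfile(fileext = ".json")
  jsonlite::write_json(spec, spec_path, auto_unbox = TRUE, digits = NA)
  script <- '
import json, sys
from openpyxl import Workbook
spec = json.load(open(sys.argv[1]))
wb = Workbook()
wb.remove(wb.active)
for sh in spec["sheets"]:
    ws = wb.create_sheet(sh["name"])
    ws.append(sh["header"])
    for row in sh["rows"]:
        ws.append(row)
wb.save(spec["path"])
'
  script_path <- tempfile(fileext = ".py")
  writeLines(script, script_path)
  status <- system2("python", c(script_path, spec_path),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(path))
    stop("workbook fixture could not be written: ",
         paste(status, collapse = "\n"))
  invisible(path)
}
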