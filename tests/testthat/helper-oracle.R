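# Independent symbolic-algebra oracle: checks rational-form identities and
# species placement with a generic computer-algebra engine (sympy via the
# system python), entirely separate from the package's own tree walkers.

sympy_oracle_script <- '
import json, sys
from sympy.parsing.sympy_parser import (parse_expr, standard_transformations,
                                        convert_xor)
import sympy as sp

TR = standard_transformations + (convert_xor,)

records = json.load(open(sys.argv[1]))
out = []
for rec in records:
    expr = parse_expr(rec["expr"], transformations=TR, evaluate=True)
    num = parse_expr(rec["num"], transformations=TR, evaluate=True)
    den = parse_expr(rec["den"], transformations=TR, evaluate=True)
    species = set(rec["species"])
    equiv = sp.simplify(sp.together(expr - num / den)) == 0
    frac_den = sp.fraction(sp.cancel(sp.together(expr)))[1]
    den_sp = bool(species & {str(s) for s in frac_den.free_symbols})
    census = sorted(species & {str(s) for s in expr.free_symbols})
    out.append({"id": rec["id"], "equiv": bool(equiv),
                "den_species": den_sp, "census": census})
json.dump(out, open(sys.argv[2], "w"))
'

run_sympy_oracle <- function(records) {
  script <- tempfile(fileext = ".py")
  writeLines(sympy_oracle_script, script)
  inp <- tempfile(fileext = ".json")
  outp <- tempfile(fileext = ".json")
  jsonlite::write_json(records, inp, auto_unbox = TRUE)
  status <- system2("python", c(script, inp, outp), stdout = TRUE,
                    stderr = TRUE)
  if (!file.exists(outp)) {
    stop("sympy oracle failed: ", paste(status, collapse = "\n"))
  }
  jsonlite::read_json(outp, simplifyVector = FALSE)
}

# Rename identifiers to neutral v<i> names so the oracle never collides
# with engine-reserved single letters (E, I, S, N, ...).
neutralize_symbols <- function(e, species) {
  vars <- sort(all.vars(e))
  map <- stats::setNames(sprintf("v%d", seq_along(vars)), vars)
  list(expr = kinclass:::substitute_symbols(e, as.list(map)),
       species = unname(map[intersect(vars, species)]))
}
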