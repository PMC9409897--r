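"""Independent LP reference solve (scipy HiGHS) for cross-checking FBA.

Input (argv[1], JSON): either a single instance
  {"S": [[...]], "lb": [...], "ub": [...], "obj": [...]}
or a batch {"instances": [instance, ...]}.
Each instance is solved as: maximize obj'v  s.t.  S v = 0, lb <= v <= ub.
Output (argv[2], JSON): {"status": ..., "objective": ...} or
{"results": [...]} for a batch.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def solve(inst):
    S = np.atleast_2d(np.array(inst["S"], dtype=float))
    obj = np.array(inst["obj"], dtype=float)
    res = linprog(
        -obj,
        A_eq=S,
        b_eq=np.zeros(S.shape[0]),
        bounds=list(zip(inst["lb"], inst["ub"])),
        method="highs",
    )
    status = {0: "optimal", 2: "infeasible", 3: "unbounded"}.get(res.status, "error")
    return {"status": status, "objective": (-res.fun) if res.status == 0 else None}


def main() -> None:
    with open(sys.argv[1]) as fh:
        d = json.load(fh)
    out = {"results": [solve(i) for i in d["instances"]]} if "instances" in d else solve(d)
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
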