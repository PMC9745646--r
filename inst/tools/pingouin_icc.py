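"""Reference ICC(A,k) computation via pingouin, used as an independent
cross-check in the test suite.

Reads a long CSV (matrix_id,subject,rater,y) from argv[1], writes a CSV
(matrix_id,icc,ci_low,ci_high) to argv[2]. The confidence bounds are as
pingouin reports them (rounded to two decimals by pingouin itself).
"""
import sys

import pandas as pd
import pingouin as pg


def main(inp, outp):
    df = pd.read_csv(inp)
    rows = []
    for mid, g in df.groupby("matrix_id", sort=True):
        res = pg.intraclass_corr(data=g, targets="subject", raters="rater",
                                 ratings="y")
        row = res[res["Type"] == "ICC(A,k)"].iloc[0]
        ci = row["CI95"] if "CI95" in res.columns else row["CI95%"]
        rows.append({"matrix_id": mid, "icc": row["ICC"],
                     "ci_low": ci[0], "ci_high": ci[1]})
    pd.DataFrame(rows).to_csv(outp, index=False)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
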