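"""Batch JPEG 2000 encode/decode helper driven by the R package.

Reads a JSON job file and writes a JSON result file.  Images travel as
16-bit single-channel TIFF; codestreams as raw .j2k (or .jp2 by extension).

Usage: python j2k_tool.py JOBFILE OUTFILE

Job file schema:
  {"jobs": [
     {"id": 1, "op": "encode", "src": "in.tif", "dst": "out.j2k",
      "rate": 100.0, "lossless": false},
     {"id": 2, "op": "decode", "src": "in.j2k", "dst": "out.tif"}
  ]}

Encode `rate` is the compression ratio requested from the encoder
(OpenJPEG quality layer); the caller owns rate control.
"""
import json
import os
import sys

import numpy as np
import tifffile
from PIL import Image


def run_job(job):
    if job["op"] == "encode":
        arr = tifffile.imread(job["src"])
        if arr.dtype != np.uint16:
            arr = arr.astype(np.uint16)
        im = Image.fromarray(arr)
        if job.get("lossless"):
            im.save(job["dst"], "JPEG2000", irreversible=False)
        else:
            im.save(job["dst"], "JPEG2000", quality_mode="rates",
                    quality_layers=[float(job["rate"])], irreversible=True)
        return {"id": job["id"], "bytes": os.path.getsize(job["dst"])}
    if job["op"] == "decode":
        im = Image.open(job["src"])
        im.load()
        arr = np.asarray(im).astype(np.uint16)
        tifffile.imwrite(job["dst"], arr)
        return {"id": job["id"], "height": int(arr.shape[0]),
                "width": int(arr.shape[1])}
    raise ValueError("unknown op: %r" % job["op"])


def main(jobfile, outfile):
    with open(jobfile) as fh:
        spec = json.load(fh)
    results = []
    for job in spec["jobs"]:
        try:
            results.append(run_job(job))
        except Exception as exc:  # reported to R, which raises with context
            results.append({"id": job["id"], "error": "%s: %s"
                            % (type(exc).__name__, exc)})
    with open(outfile, "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
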