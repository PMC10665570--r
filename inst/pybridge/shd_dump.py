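"""Dump an SHD-schema HDF5 spike file to a plain-text stream.

Usage: python shd_dump.py <in.h5> <out.txt>

Output format:
  line 1: n_samples
  then per sample: "<label> <n_events>" / times (seconds, full precision) /
  unit indices, each on one whitespace-separated line (empty line when the
  sample has no events).
"""
import sys

import h5py
import numpy as np


def main(path, out):
    with h5py.File(path, "r") as f:
        for key in ("spikes/times", "spikes/units", "labels"):
            if key not in f:
                sys.stderr.write("MISSING /%s\n" % key)
                return 2
        times = f["spikes/times"]
        units = f["spikes/units"]
        labels = np.asarray(f["labels"][...]).astype(int)
        if len(times) != len(labels) or len(units) != len(labels):
            sys.stderr.write("LENGTH MISMATCH between spikes and labels\n")
            return 2
        with open(out, "w") as o:
            o.write("%d\n" % len(labels))
            for i in range(len(labels)):
                t = np.asarray(times[i], dtype=float).ravel()
                u = np.asarray(units[i], dtype=int).ravel()
                if len(t) != len(u):
                    sys.stderr.write("LENGTH MISMATCH in sample %d\n" % i)
                    return 2
                o.write("%d %d\n" % (labels[i], len(t)))
                o.write(" ".join(repr(float(x)) for x in t) + "\n")
                o.write(" ".join(str(int(x)) for x in u) + "\n")
    return 0


if __name__ == "__main__":
    if len(sys.argv) != 3:
        sys.stderr.write("usage: shd_dump.py <in.h5> <out.txt>\n")
        sys.exit(2)
    sys.exit(main(sys.argv[1], sys.argv[2]))
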