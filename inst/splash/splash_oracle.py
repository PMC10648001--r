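#!/usr/bin/env python3
"""Independent implementation of the SPLASH spectral-hash protocol used for
cross-checking the R implementation.

Reads one spectrum per line on stdin, formatted as
"mz1:int1 mz2:int2 ...", and prints one SPLASH per line.

Protocol (mass-spectrum flavour, version 0):
  block 1: "splash10"
  block 2: 10 wrapped 5-Da intensity bins -> base-3 digits -> base-36,
           zero-padded to 4 chars
  block 3: 10 wrapped 100-Da intensity bins -> base-10 digit string
  block 4: sha256 over "round(mz*1e6):round(999*I/Imax)" pairs sorted by
           (mz asc, intensity desc), joined by single spaces; first 20 hex
           chars
"""
import hashlib
import sys

EPS = 1e-7
ALPHABET = "0123456789abcdefghijklmnopqrstuvwxyz"


def histogram(peaks, base, nbins, bin_size):
    h = [0.0] * nbins
    for mz, inten in peaks:
        h[int(mz // bin_size) % nbins] += inten
    m = max(h)
    if m <= 0:
        return [0] * nbins
    return [int(EPS + (base - 1) * x / m) for x in h]


def to_base36(digits, base, width):
    val = 0
    for d in digits:
        val = val * base + d
    out = ""
    while val > 0:
        out = ALPHABET[val % 36] + out
        val //= 36
    return out.rjust(width, "0")


def splash(peaks):
    b2 = to_base36(histogram(peaks, 3, 10, 5), 3, 4)
    b3 = "".join(str(d) for d in histogram(peaks, 10, 10, 100))
    imax = max(i for _, i in peaks)
    ions = sorted(peaks, key=lambda p: (p[0], -p[1]))
    payload = " ".join(
        "%.0f:%.0f" % (round(mz * 1e6), round(999 * inten / imax))
        for mz, inten in ions
    )
    b4 = hashlib.sha256(payload.encode("utf-8")).hexdigest()[:20]
    return "-".join(["splash10", b2, b3, b4])


def main():
    for line in sys.stdin:
        line = line.strip()
        if not line:
            continue
        peaks = [tuple(map(float, tok.split(":"))) for tok in line.split()]
        print(splash(peaks))


if __name__ == "__main__":
    main()
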