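#!/usr/bin/env python
"""Independent reference implementation of the flexible-cylinder form factor.

Evaluates the method-3 wormlike-chain scattering function with
excluded-volume corrections (Pedersen-Schurtenberger parameterization)
times the circular cross-section factor [2 J1(qR)/(qR)]^2, normalized to 1
at q -> 0. Written against the same published equations as the R
implementation but coded independently (numpy/scipy), so the two can be
cross-checked.

Usage: wlc_reference.py L b R qfile
  L, b, R in Angstrom; qfile holds one q value (1/A) per line.
Prints one normalized intensity per q value.
"""
import sys

import numpy as np
from scipy.special import j1, sici


def alpha_sq(n):
    return (1.0 + (n / 3.12) ** 2 + (n / 8.67) ** 3) ** (0.176 / 3.0)


def rg2_long(L, b):
    return alpha_sq(L / b) * L * b / 6.0


def rg2_short(L, b):
    n = L / b
    if n < 0.05:
        fac = n / 2.0 - n * n / 5.0
    else:
        fac = 1.0 - 1.5 / n + 1.5 / n**2 - 0.75 / n**3 * (1.0 - np.exp(-2.0 * n))
    return rg2_long(L, b) * fac


def debye(u):
    u = np.asarray(u, dtype=float)
    out = np.empty_like(u)
    small = u < 1e-3
    out[small] = 1.0 - u[small] / 3.0 + u[small] ** 2 / 12.0
    ub = u[~small]
    out[~small] = 2.0 * (np.exp(-ub) + ub - 1.0) / ub**2
    return out


def w_cross(x):
    # clamped to 0 below x = 1: the power-law branch it switches on
    # diverges like x**(-3/nu) there while the tanh tends to a small
    # positive constant
    w = 0.5 * (1.0 + np.tanh((x - 1.523) / 0.1477))
    return np.where(x < 1.0, 0.0, w)


def sexv_raw(q, rg):
    qr = q * rg
    w = w_cross(qr)
    t = qr ** (-1.0 / 0.585)
    return (1.0 - w) * debye(qr**2) + w * (
        1.22 * t + 0.4288 * t**2 - 1.651 * t**3
    )


def sexv_envelope(q, rg):
    """Running minimum of sexv_raw in q (dense internal grid)."""
    qrmax = max(float(np.max(q)) * rg, 0.02)
    grid = np.exp(np.linspace(np.log(0.01), np.log(qrmax), 1000)) / rg
    qall = np.unique(np.concatenate([np.atleast_1d(q), grid]))
    env = np.minimum.accumulate(sexv_raw(qall, rg))
    idx = np.searchsorted(qall, q)
    return env[idx]


def stiffness_corr(u):
    u = np.asarray(u, dtype=float)
    out = np.empty_like(u)
    small = u < 1e-4
    out[small] = 7.0 / 15.0 + 8.0 * u[small] / 15.0
    ub = u[~small]
    out[~small] = (
        4.0 / 15.0
        + 7.0 / (15.0 * ub)
        - (11.0 / 15.0 + 7.0 / (15.0 * ub)) * np.exp(-2.0 * ub)
    )
    return out


def join_coeffs(slow, qc, b, L, p1, p2):
    """Two-term power law joined with value+slope continuity at qc."""
    delta = 1.001
    s1 = float(slow(np.array([qc]))[0])
    s2 = float(slow(np.array([qc * delta]))[0])
    ds = (s2 - s1) / (qc * (delta - 1.0))
    xc = qc * b
    amat = np.array(
        [
            [xc**-p1, xc**-p2],
            [-(p1 / qc) * xc**-p1, -(p2 / qc) * xc**-p2],
        ]
    )
    rhs = np.array([s1 - np.pi / (qc * L), ds + np.pi / (qc**2 * L)])
    return np.linalg.solve(amat, rhs)


def p_rod(u):
    u = np.asarray(u, dtype=float)
    out = np.empty_like(u)
    small = u < 1e-3
    out[small] = 1.0 - u[small] ** 2 / 36.0
    ub = u[~small]
    si = sici(ub)[0]
    out[~small] = 2.0 * si / ub - 4.0 * np.sin(ub / 2.0) ** 2 / ub**2
    return out


def s_wlc(q, L, b):
    q = np.asarray(q, dtype=float)
    n = L / b
    if n > 4.0:
        rg2 = rg2_long(L, b)
        c_corr = 3.06 * n ** (-0.44) if n > 10.0 else 1.0

        def slow(qq):
            u = qq**2 * rg2
            return sexv_envelope(qq, np.sqrt(rg2)) + c_corr * (
                b / L
            ) * stiffness_corr(u)

        qc = 3.1 / b
        p1, p2 = 4.12, 4.42
        a1, a2 = join_coeffs(slow, qc, b, L, p1, p2)
        out = np.empty_like(q)
        lo = q * b <= 3.1
        out[lo] = slow(q[lo])
        x = q[~lo] * b
        out[~lo] = a1 * x**-p1 + a2 * x**-p2 + np.pi / (q[~lo] * L)
        return out / (1.0 + c_corr * (b / L) * 7.0 / 15.0)
    lam = min(max((4.0 - n) / 3.0, 0.0), 1.0)
    rod = p_rod(q * L)
    if lam >= 1.0:
        return rod
    rg2s = rg2_short(L, b)
    rgs = np.sqrt(rg2s)
    qcb = max(1.9 * b / rgs, 3.0)
    qc = qcb / b
    p1, p2 = 5.36, 5.62

    def sdeb(qq):
        return debye(qq**2 * rg2s)

    a1, a2 = join_coeffs(sdeb, qc, b, L, p1, p2)
    x = q * b
    ps = np.where(
        x <= qcb, sdeb(q), a1 * x**-p1 + a2 * x**-p2 + np.pi / (q * L)
    )
    return lam * rod + (1.0 - lam) * ps


def p_cross_section(x):
    x = np.asarray(x, dtype=float)
    out = np.empty_like(x)
    small = np.abs(x) < 1e-4
    out[small] = 1.0 - x[small] ** 2 / 4.0
    xb = x[~small]
    out[~small] = (2.0 * j1(xb) / xb) ** 2
    return out


def main(argv):
    if len(argv) != 5:
        sys.stderr.write(__doc__)
        return 2
    L, b, R = (float(a) for a in argv[1:4])
    q = np.loadtxt(argv[4], ndmin=1)
    p = s_wlc(q, L, b) * p_cross_section(q * R)
    for v in p:
        sys.stdout.write("%.12e\n" % v)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
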