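#!/usr/bin/env python
"""Independent reference transcription of the O'Hara-Rudy dynamic (ORd)
human ventricular myocyte model (endo / M / epi variants).

Plain-Python brute-force oracle used by the test suite's frozen expected
values: paced at a fixed cycle length with the same hybrid integration
scheme as the package core (exponential updates for relaxation-form
variables, forward Euler for Vm / concentrations / CaMK), it reports the
per-beat APD90.  Transcribed separately from the compiled implementation so
the two can be cross-checked.

Usage: python ord_reference.py <celltype> <n_beats> [cl_ms] [dt_ms]
Prints one APD90 (ms) per beat.
"""
import math
import sys

ENDO, EPI, M = 0, 1, 2
NAO, CAO, KO = 140.0, 1.8, 5.4
R, T, F = 8314.0, 310.0, 96485.0
L, RAD = 0.01, 0.0011
VCELL = 1000 * 3.14 * RAD * RAD * L
AGEO = 2 * 3.14 * RAD * RAD + 2 * 3.14 * RAD * L
ACAP = 2 * AGEO
VMYO, VNSR, VJSR, VSS = 0.68 * VCELL, 0.0552 * VCELL, 0.0048 * VCELL, 0.02 * VCELL


def initial_state():
    return dict(v=-87.0, nai=7.0, nass=7.0, ki=145.0, kss=145.0,
                cai=1e-4, cass=1e-4, cansr=1.2, cajsr=1.2,
                m=0.0, hf=1.0, hs=1.0, j=1.0, hsp=1.0, jp=1.0,
                mL=0.0, hL=1.0, hLp=1.0,
                a=0.0, iF=1.0, iS=1.0, ap=0.0, iFp=1.0, iSp=1.0,
                d=0.0, ff=1.0, fs=1.0, fcaf=1.0, fcas=1.0, jca=1.0,
                nca=0.0, ffp=1.0, fcafp=1.0,
                xrf=0.0, xrs=0.0, xs1=0.0, xs2=0.0, xk1=1.0,
                Jrelnp=0.0, Jrelp=0.0, CaMKt=0.0)


def step(y, ct, dt, istim):
    exp = math.exp
    v = y['v']
    vfrt = v * F / (R * T)
    rtf = R * T / F

    CaMKb = 0.05 * (1 - y['CaMKt']) / (1 + 0.0015 / y['cass'])
    CaMKa = CaMKb + y['CaMKt']
    dCaMKt = 0.05 * CaMKb * (CaMKb + y['CaMKt']) - 0.00068 * y['CaMKt']
    phi = 1.0 / (1.0 + 0.15 / CaMKa)   # CaMK-phosphorylated fraction

    ENa = rtf * math.log(NAO / y['nai'])
    EK = rtf * math.log(KO / y['ki'])
    EKs = rtf * math.log((KO + 0.01833 * NAO) / (y['ki'] + 0.01833 * y['nai']))

    relax = {}  # name -> (steady state, tau)

    # INa
    mss = 1 / (1 + exp(-(v + 39.57) / 9.871))
    tm = 1 / (6.765 * exp((v + 11.64) / 34.77) + 8.552 * exp(-(v + 77.42) / 5.955))
    relax['m'] = (mss, tm)
    hss = 1 / (1 + exp((v + 82.90) / 6.086))
    thf = 1 / (1.432e-5 * exp(-(v + 1.196) / 6.285) + 6.149 * exp((v + 0.5096) / 20.27))
    ths = 1 / (0.009794 * exp(-(v + 17.95) / 28.05) + 0.3343 * exp((v + 5.730) / 56.66))
    relax['hf'] = (hss, thf)
    relax['hs'] = (hss, ths)
    h = 0.99 * y['hf'] + 0.01 * y['hs']
    tj = 2.038 + 1 / (0.02136 * exp(-(v + 100.6) / 8.281) + 0.3052 * exp((v + 0.9941) / 38.45))
    relax['j'] = (hss, tj)
    hssp = 1 / (1 + exp((v + 89.1) / 6.086))
    relax['hsp'] = (hssp, 3 * ths)
    hp = 0.99 * y['hf'] + 0.01 * y['hsp']
    relax['jp'] = (hss, 1.46 * tj)
    GNa = 75.0
    INa = GNa * (v - ENa) * y['m'] ** 3 * ((1 - phi) * h * y['j'] + phi * hp * y['jp'])

    # INaL
    mLss = 1 / (1 + exp(-(v + 42.85) / 5.264))
    relax['mL'] = (mLss, tm)
    hLss = 1 / (1 + exp((v + 87.61) / 7.488))
    relax['hL'] = (hLss, 200.0)
    hLssp = 1 / (1 + exp((v + 93.81) / 7.488))
    relax['hLp'] = (hLssp, 600.0)
    GNaL = 0.0075 * (0.6 if ct == EPI else 1.0)
    INaL = GNaL * (v - ENa) * y['mL'] * ((1 - phi) * y['hL'] + phi * y['hLp'])

    # Ito
    ass = 1 / (1 + exp(-(v - 14.34) / 14.82))
    ta = 1.0515 / (1 / (1.2089 * (1 + exp(-(v - 18.4099) / 29.3814)))
                   + 3.5 / (1 + exp((v + 100) / 29.3814)))
    relax['a'] = (ass, ta)
    iss = 1 / (1 + exp((v + 43.94) / 5.711))
    depi = 1 - 0.95 / (1 + exp((v + 70) / 5.0)) if ct == EPI else 1.0
    tiF = depi * (4.562 + 1 / (0.3933 * exp(-(v + 100) / 100) + 0.08004 * exp((v + 50) / 16.59)))
    tiS = depi * (23.62 + 1 / (0.001416 * exp(-(v + 96.52) / 59.05) + 1.78e-8 * exp((v + 114.1) / 8.079)))
    relax['iF'] = (iss, tiF)
    relax['iS'] = (iss, tiS)
    AiF = 1 / (1 + exp((v - 213.6) / 151.2))
    ito_i = AiF * y['iF'] + (1 - AiF) * y['iS']
    assp = 1 / (1 + exp(-(v - 24.34) / 14.82))
    relax['ap'] = (assp, ta)
    dev = 1.354 + 1e-4 / (exp((v - 167.4) / 15.89) + exp(-(v - 12.23) / 0.2154))
    rec = 1 - 0.5 / (1 + exp((v + 70) / 20))
    relax['iFp'] = (iss, dev * rec * tiF)
    relax['iSp'] = (iss, dev * rec * tiS)
    ito_ip = AiF * y['iFp'] + (1 - AiF) * y['iSp']
    Gto = 0.02 * (4.0 if ct in (EPI, M) else 1.0)
    Ito = Gto * (v - EK) * ((1 - phi) * y['a'] * ito_i + phi * y['ap'] * ito_ip)

    # ICaL family
    dss = 1 / (1 + exp(-(v + 3.940) / 4.230))
    td = 0.6 + 1 / (exp(-0.05 * (v + 6)) + exp(0.09 * (v + 14)))
    relax['d'] = (dss, td)
    fss = 1 / (1 + exp((v + 19.58) / 3.696))
    tff = 7 + 1 / (0.0045 * exp(-(v + 20) / 10) + 0.0045 * exp((v + 20) / 10))
    tfs = 1000 + 1 / (3.5e-5 * exp(-(v + 5) / 4) + 3.5e-5 * exp((v + 5) / 6))
    relax['ff'] = (fss, tff)
    relax['fs'] = (fss, tfs)
    f = 0.6 * y['ff'] + 0.4 * y['fs']
    tfcaf = 7 + 1 / (0.04 * exp(-(v - 4) / 7) + 0.04 * exp((v - 4) / 7))
    tfcas = 100 + 1 / (0.00012 * exp(-v / 3) + 0.00012 * exp(v / 7))
    Afcaf = 0.3 + 0.6 / (1 + exp((v - 10) / 10))
    relax['fcaf'] = (fss, tfcaf)
    relax['fcas'] = (fss, tfcas)
    fca = Afcaf * y['fcaf'] + (1 - Afcaf) * y['fcas']
    relax['jca'] = (fss, 75.0)
    relax['ffp'] = (fss, 2.5 * tff)
    fp = 0.6 * y['ffp'] + 0.4 * y['fs']
    relax['fcafp'] = (fss, 2.5 * tfcaf)
    fcap = Afcaf * y['fcafp'] + (1 - Afcaf) * y['fcas']
    km2n = y['jca']
    anca = 1 / (1000.0 / km2n + (1 + 0.002 / y['cass']) ** 4)
    relax['nca'] = (anca * 1000.0 / km2n, 1.0 / km2n)
    ex2 = exp(2 * vfrt)
    ex1 = exp(vfrt)
    PhiCaL = 4 * vfrt * F * (y['cass'] * ex2 - 0.341 * CAO) / (ex2 - 1)
    PhiCaNa = vfrt * F * (0.75 * y['nass'] * ex1 - 0.75 * NAO) / (ex1 - 1)
    PhiCaK = vfrt * F * (0.75 * y['kss'] * ex1 - 0.75 * KO) / (ex1 - 1)
    PCa = 0.0001 * (1.2 if ct == EPI else 2.5 if ct == M else 1.0)
    gnp = y['d'] * (f * (1 - y['nca']) + y['jca'] * fca * y['nca'])
    gp = y['d'] * (fp * (1 - y['nca']) + y['jca'] * fcap * y['nca'])
    ICaL = (1 - phi) * PCa * PhiCaL * gnp + phi * 1.1 * PCa * PhiCaL * gp
    ICaNa = (1 - phi) * 0.00125 * PCa * PhiCaNa * gnp + phi * 0.00125 * 1.1 * PCa * PhiCaNa * gp
    ICaK = (1 - phi) * 3.574e-4 * PCa * PhiCaK * gnp + phi * 3.574e-4 * 1.1 * PCa * PhiCaK * gp

    # IKr
    xrss = 1 / (1 + exp(-(v + 8.337) / 6.789))
    txrf = 12.98 + 1 / (0.3652 * exp((v - 31.66) / 3.869) + 4.123e-5 * exp(-(v - 47.78) / 20.38))
    txrs = 1.865 + 1 / (0.06629 * exp((v - 34.70) / 7.355) + 1.128e-5 * exp(-(v - 29.74) / 25.94))
    relax['xrf'] = (xrss, txrf)
    relax['xrs'] = (xrss, txrs)
    Axrf = 1 / (1 + exp((v + 54.81) / 38.21))
    xr = Axrf * y['xrf'] + (1 - Axrf) * y['xrs']
    rkr = 1 / ((1 + exp((v + 55) / 75)) * (1 + exp((v - 10) / 30)))
    GKr = 0.046 * (1.3 if ct == EPI else 0.8 if ct == M else 1.0)
    IKr = GKr * math.sqrt(KO / 5.4) * xr * rkr * (v - EK)

    # IKs
    xs1ss = 1 / (1 + exp(-(v + 11.60) / 8.932))
    txs1 = 817.3 + 1 / (2.326e-4 * exp((v + 48.28) / 17.80) + 0.001292 * exp(-(v + 210) / 230))
    relax['xs1'] = (xs1ss, txs1)
    txs2 = 1 / (0.01 * exp((v - 50) / 20) + 0.0193 * exp(-(v + 66.54) / 31))
    relax['xs2'] = (xs1ss, txs2)
    KsCa = 1 + 0.6 / (1 + (3.8e-5 / y['cai']) ** 1.4)
    GKs = 0.0034 * (1.4 if ct == EPI else 1.0)
    IKs = GKs * KsCa * y['xs1'] * y['xs2'] * (v - EKs)

    # IK1
    xk1ss = 1 / (1 + exp(-(v + 2.5538 * KO + 144.59) / (1.5692 * KO + 3.8115)))
    txk1 = 122.2 / (exp(-(v + 127.2) / 20.36) + exp((v + 236.8) / 69.33))
    relax['xk1'] = (xk1ss, txk1)
    rk1 = 1 / (1 + exp((v + 105.8 - 2.6 * KO) / 9.493))
    GK1 = 0.1908 * (1.2 if ct == EPI else 1.3 if ct == M else 1.0)
    IK1 = GK1 * math.sqrt(KO) * rk1 * y['xk1'] * (v - EK)

    # INaCa (shared kinetic core)
    def inaca(na, ca, frac):
        kna1, kna2, kna3 = 15.0, 5.0, 88.12
        kasymm, wna, wca, wnaca = 12.5, 6.0e4, 6.0e4, 5.0e3
        kcaon, kcaoff = 1.5e6, 5.0e3
        hca = exp(0.1670 * vfrt)
        hna = exp(0.5224 * vfrt)
        h1 = 1 + na / kna3 * (1 + hna)
        h2 = na * hna / (kna3 * h1)
        h3 = 1 / h1
        h4 = 1 + na / kna1 * (1 + na / kna2)
        h5 = na * na / (h4 * kna1 * kna2)
        h6 = 1 / h4
        h7 = 1 + NAO / kna3 * (1 + 1 / hna)
        h8 = NAO / (kna3 * hna * h7)
        h9 = 1 / h7
        h10 = kasymm + 1 + NAO / kna1 * (1 + NAO / kna2)
        h11 = NAO * NAO / (h10 * kna1 * kna2)
        h12 = 1 / h10
        k1 = h12 * CAO * kcaon
        k2 = kcaoff
        k3p_ = h9 * wca
        k3pp = h8 * wnaca
        k3 = k3p_ + k3pp
        k4p_ = h3 * wca / hca
        k4pp = h2 * wnaca
        k4 = k4p_ + k4pp
        k5 = kcaoff
        k6 = h6 * ca * kcaon
        k7 = h5 * h2 * wna
        k8 = h8 * h11 * wna
        x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3)
        x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8)
        x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3)
        x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8)
        s = x1 + x2 + x3 + x4
        E1, E2, E3, E4 = x1 / s, x2 / s, x3 / s, x4 / s
        allo = 1 / (1 + (150e-6 / ca) ** 2)
        JNa = 3 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp
        JCa = E2 * k2 - E1 * k1
        Gncx = 0.0008 * (1.1 if ct == EPI else 1.4 if ct == M else 1.0)
        return frac * Gncx * allo * (JNa + 2 * JCa)
    INaCa_i = inaca(y['nai'], y['cai'], 0.8)
    INaCa_ss = inaca(y['nass'], y['cass'], 0.2)

    # INaK
    Knai = 9.073 * exp(-0.1550 * vfrt / 3)
    Knao = 27.78 * exp(1.1550 * vfrt / 3)
    P = 4.2 / (1 + 1e-7 / 1.698e-7 + y['nai'] / 224.0 + y['ki'] / 292.0)
    di = (1 + y['nai'] / Knai) ** 3 + (1 + y['ki'] / 0.5) ** 2 - 1
    do_ = (1 + NAO / Knao) ** 3 + (1 + KO / 0.3582) ** 2 - 1
    a1 = 949.5 * (y['nai'] / Knai) ** 3 / di
    b1 = 182.4 * 0.05
    a2 = 687.2
    b2 = 39.4 * (NAO / Knao) ** 3 / do_
    a3 = 1899.0 * (KO / 0.3582) ** 2 / do_
    b3 = 79300.0 * P * 1e-7 / (1 + 9.8 / 1.698e-7)
    a4 = (639.0 * 9.8 / 1.698e-7) / (1 + 9.8 / 1.698e-7)
    b4 = 40.0 * (y['ki'] / 0.5) ** 2 / di
    x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2
    x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4
    x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1
    x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b2 * a1
    s = x1 + x2 + x3 + x4
    E1, E2, E3, E4 = x1 / s, x2 / s, x3 / s, x4 / s
    Pnak = 30.0 * (0.9 if ct == EPI else 0.7 if ct == M else 1.0)
    INaK = Pnak * (3 * (E1 * a3 - E2 * b3) + 2 * (E4 * b1 - E3 * a1))

    # minor currents
    xkb = 1 / (1 + exp(-(v - 14.48) / 18.34))
    IKb = 0.003 * (0.6 if ct == EPI else 1.0) * xkb * (v - EK)
    INab = 3.75e-10 * vfrt * F * (y['nai'] * ex1 - NAO) / (ex1 - 1)
    ICab = 2.5e-8 * 4 * vfrt * F * (y['cai'] * ex2 - 0.341 * CAO) / (ex2 - 1)
    IpCa = 0.0005 * y['cai'] / (0.0005 + y['cai'])

    # fluxes
    JdiffNa = (y['nass'] - y['nai']) / 2.0
    JdiffK = (y['kss'] - y['ki']) / 2.0
    Jdiff = (y['cass'] - y['cai']) / 0.2
    bt = 4.75
    gate = 1 + (1.5 / y['cajsr']) ** 8
    relf = 1.7 if ct == M else 1.0
    Jrel_inf = relf * 0.5 * bt * (-ICaL) / gate
    trel = max(bt / (1 + 0.0123 / y['cajsr']), 0.001)
    relax['Jrelnp'] = (Jrel_inf, trel)
    btp = 1.25 * bt
    Jrel_infp = relf * 0.5 * btp * (-ICaL) / gate
    trelp = max(btp / (1 + 0.0123 / y['cajsr']), 0.001)
    relax['Jrelp'] = (Jrel_infp, trelp)
    Jrel = (1 - phi) * y['Jrelnp'] + phi * y['Jrelp']
    upf = 1.3 if ct == EPI else 1.0
    Jupnp = upf * 0.004375 * y['cai'] / (y['cai'] + 0.00092)
    Jupp = upf * 2.75 * 0.004375 * y['cai'] / (y['cai'] + 0.00092 - 0.00017)
    Jleak = 0.0039375 * y['cansr'] / 15.0
    Jup = (1 - phi) * Jupnp + phi * Jupp - Jleak
    Jtr = (y['cansr'] - y['cajsr']) / 100.0

    # balances
    dnai = -(INa + INaL + 3 * INaCa_i + 3 * INaK + INab) * ACAP / (F * VMYO) + JdiffNa * VSS / VMYO
    dnass = -(ICaNa + 3 * INaCa_ss) * ACAP / (F * VSS) - JdiffNa
    dki = -(Ito + IKr + IKs + IK1 + IKb + istim - 2 * INaK) * ACAP / (F * VMYO) + JdiffK * VSS / VMYO
    dkss = -ICaK * ACAP / (F * VSS) - JdiffK
    cmdn = 0.05 * (1.3 if ct == EPI else 1.0)
    Bcai = 1 / (1 + cmdn * 0.00238 / (0.00238 + y['cai']) ** 2
                + 0.07 * 0.0005 / (0.0005 + y['cai']) ** 2)
    dcai = Bcai * (-(IpCa + ICab - 2 * INaCa_i) * ACAP / (2 * F * VMYO)
                   - Jup * VNSR / VMYO + Jdiff * VSS / VMYO)
    Bcass = 1 / (1 + 0.047 * 0.00087 / (0.00087 + y['cass']) ** 2
                 + 1.124 * 0.0087 / (0.0087 + y['cass']) ** 2)
    dcass = Bcass * (-(ICaL - 2 * INaCa_ss) * ACAP / (2 * F * VSS)
                     + Jrel * VJSR / VSS - Jdiff)
    dcansr = Jup - Jtr * VJSR / VNSR
    Bcajsr = 1 / (1 + 10.0 * 0.8 / (0.8 + y['cajsr']) ** 2)
    dcajsr = Bcajsr * (Jtr - Jrel)
    Iion = (INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1
            + INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa + ICab)

    # advance: exponential for relaxation variables, Euler for the rest
    for k, (yss, tau) in relax.items():
        y[k] = yss - (yss - y[k]) * math.exp(-dt / tau)
    y['v'] += dt * (-(Iion + istim))
    y['nai'] += dt * dnai
    y['nass'] += dt * dnass
    y['ki'] += dt * dki
    y['kss'] += dt * dkss
    y['cai'] += dt * dcai
    y['cass'] += dt * dcass
    y['cansr'] += dt * dcansr
    y['cajsr'] += dt * dcajsr
    y['CaMKt'] += dt * dCaMKt
    return y


def pace(celltype, n_beats, cl=1000.0, dt=0.005, amp=-80.0, dur=0.5):
    ct = {'endo': ENDO, 'epi': EPI, 'M': M}[celltype]
    y = initial_state()
    steps = int(round(cl / dt))
    apds = []
    for _ in range(n_beats):
        vrest = y['v']
        vpeak = y['v']
        maxdv, tup, tcross = -1e300, None, None
        crossed = False
        for s in range(steps):
            t = s * dt
            vold = y['v']
            step(y, ct, dt, amp if t < dur else 0.0)
            dv = (y['v'] - vold) / dt
            if dv > maxdv:
                maxdv, tup = dv, t + dt
            if y['v'] > vpeak:
                vpeak = y['v']
            if not crossed and y['v'] < vold:
                v90 = vpeak - 0.9 * (vpeak - vrest)
                if y['v'] < v90 and vpeak - vrest > 20:
                    tcross, crossed = t + dt, True
        apds.append(tcross - tup if crossed and tup is not None else float('nan'))
    return apds


if __name__ == '__main__':
    celltype = sys.argv[1]
    n_beats = int(sys.argv[2])
    cl = float(sys.argv[3]) if len(sys.argv) > 3 else 1000.0
    dt = float(sys.argv[4]) if len(sys.argv) > 4 else 0.005
    for a in pace(celltype, n_beats, cl, dt):
        print('%.6f' % a)
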