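#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <utility>

using namespace Rcpp;

// Speed of light in vacuum, mm/ps
static const double C_MM_PS = 0.299792458;

// ---------------------------------------------------------------------------
// Counter-based RNG: one splitmix64 stream per photon index, derived from the
// master seed, so results are independent of batch partitioning.
// ---------------------------------------------------------------------------
static inline uint64_t sm64_next(uint64_t &state) {
    state += 0x9E3779B97F4A7C15ULL;
    uint64_t z = state;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
}

static inline double runif01(uint64_t &state) {
    // in [0, 1)
    return (double)(sm64_next(state) >> 11) * (1.0 / 9007199254740992.0);
}

static inline uint64_t photon_stream(double seed, int i) {
    uint64_t s = (uint64_t)((int64_t)seed);
    uint64_t st = s * 0x9E3779B97F4A7C15ULL ^
        (0xD1B54A32D192ED03ULL * (uint64_t)(i + 1));
    // warm up
    sm64_next(st);
    return st;
}

// ---------------------------------------------------------------------------
// Elementary physics helpers
// ---------------------------------------------------------------------------

// Inverse-CDF sample of cos(theta) for the Henyey-Greenstein phase function.
static inline double hg_cos(double u, double g) {
    double ct;
    if (std::fabs(g) < 1e-8) {
        ct = 2.0 * u - 1.0;
    } else {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
        ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
    }
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
    return ct;
}

// Rotate a unit direction by polar angle (cos ct) and azimuth psi in the
// local frame of the current direction (standard photon-packet construction).
static inline void rotate_dir(double *d, double ct, double psi) {
    double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
    double cp = std::cos(psi), sp = std::sin(psi);
    double ux = d[0], uy = d[1], uz = d[2];
    if (std::fabs(uz) > 0.99999) {
        d[0] = st * cp;
        d[1] = st * sp;
        d[2] = (uz >= 0.0 ? ct : -ct);
    } else {
        double den = std::sqrt(1.0 - uz * uz);
        d[0] = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        d[1] = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        d[2] = -den * st * cp + uz * ct;
    }
    double nrm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
}

// Unpolarized Fresnel reflectance for incidence cosine ci (>0), going from
// refractive index n1 to n2; returns 1 for total internal reflection.
static inline double fresnel_R(double ci, double n1, double n2) {
    if (n1 == n2) return 0.0;
    if (ci > 1.0) ci = 1.0;
    double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
    double st = n1 * si / n2;
    if (st >= 1.0) return 1.0;
    double ct = std::sqrt(1.0 - st * st);
    double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
    double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
    return 0.5 * (rs * rs + rp * rp);
}

// Snell refraction across an axis-aligned face. axis in {0,1,2}, sgn is the
// outward normal sign. Direction must be outbound (d[axis]*sgn > 0).
static inline bool snell_refract(double *d, int axis, int sgn,
                                 double n1, double n2) {
    double ci = std::fabs(d[axis]);
    double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
    double st = n1 * si / n2;
    if (st >= 1.0) return false; // total internal reflection
    double ct = std::sqrt(1.0 - st * st);
    double scale = (si > 1e-12) ? (st / si) : 0.0;
    for (int a = 0; a < 3; ++a)
        if (a != axis) d[a] *= scale;
    d[axis] = sgn * ct;
    double nrm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
    return true;
}

// Distance along dir to the exit face of voxel (ix,iy,iz); fills axis & sign.
static inline double dist_to_exit(const double *pos, const double *dir,
                                  int ix, int iy, int iz,
                                  double vx, double vy, double vz,
                                  int &axis, int &sgn) {
    double best = 1e300;
    axis = 0; sgn = 1;
    const int idx[3] = {ix, iy, iz};
    const double vs[3] = {vx, vy, vz};
    for (int a = 0; a < 3; ++a) {
        double da = dir[a];
        double t;
        if (da > 1e-12) {
            t = ((idx[a] + 1) * vs[a] - pos[a]) / da;
            if (t < best) { best = t; axis = a; sgn = 1; }
        } else if (da < -1e-12) {
            t = (idx[a] * vs[a] - pos[a]) / da;
            if (t < best) { best = t; axis = a; sgn = -1; }
        }
    }
    if (best < 0.0) best = 0.0;
    return best;
}

// ---------------------------------------------------------------------------
// Exported elementary operations (unit-testable surface of the engine)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_hg_cos(NumericVector xi, double g) {
    int n = xi.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) out[i] = hg_cos(xi[i], g);
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_hg_draws(int n, double g, double seed) {
    // seeded bulk draws from the package RNG (photon-stream convention)
    NumericVector out(n);
    uint64_t st = photon_stream(seed, 0);
    for (int i = 0; i < n; ++i) out[i] = hg_cos(runif01(st), g);
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_rotate_direction(NumericVector dir, double cos_theta,
                                   double psi) {
    double d[3] = {dir[0], dir[1], dir[2]};
    rotate_dir(d, cos_theta, psi);
    return NumericVector::create(d[0], d[1], d[2]);
}

// [[Rcpp::export]]
double cpp_fresnel(double cos_i, double n_in, double n_out) {
    return fresnel_R(cos_i, n_in, n_out);
}

// [[Rcpp::export]]
List cpp_refract(NumericVector dir, IntegerVector axis_sgn,
                 double n_in, double n_out) {
    double d[3] = {dir[0], dir[1], dir[2]};
    bool ok = snell_refract(d, axis_sgn[0], axis_sgn[1], n_in, n_out);
    return List::create(_["refracted"] = ok,
                        _["direction"] = NumericVector::create(d[0], d[1], d[2]));
}

// Single-packet free-path advance through the voxel grid: consumes an
// optical-depth budget voxel by voxel until an interaction site or an
// air/tissue surface is reached. Exposed for unit testing of the marching
// arithmetic; the full simulation inlines the same logic.
// [[Rcpp::export]]
List cpp_advance_packet(NumericVector pos0, NumericVector dir0,
                        double time0, NumericVector partial0, int visited0,
                        double budget,
                        IntegerVector labels, IntegerVector dims,
                        NumericVector voxsize,
                        NumericVector mu_t, NumericVector n_refr) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const double vx = voxsize[0], vy = voxsize[1], vz = voxsize[2];
    double pos[3] = {pos0[0], pos0[1], pos0[2]};
    double dir[3] = {dir0[0], dir0[1], dir0[2]};
    double tof = time0;
    NumericVector partial = clone(partial0);
    int visited = visited0;
    std::string outcome = "interaction";
    int axis = 0, sgn = 1;
    int ix = (int)std::floor(pos[0] / vx);
    int iy = (int)std::floor(pos[1] / vy);
    int iz = (int)std::floor(pos[2] / vz);
    int steps = 0;
    for (;;) {
        if (++steps > 100000000) stop("advance: step cap exceeded");
        if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz) {
            stop("packet escaped the grid bounding box without an air boundary: malformed volume");
        }
        int code = labels[ix + nx * (iy + ny * iz)];
        if (code == 0)
            stop("packet inside an air voxel; launch position must be in tissue");
        double mt = mu_t[code];
        double seg = dist_to_exit(pos, dir, ix, iy, iz, vx, vy, vz, axis, sgn);
        double s;
        bool interact = false;
        if (mt > 0.0 && mt * seg >= budget) {
            s = budget / mt;
            interact = true;
        } else {
            s = seg;
            budget -= mt * s;
        }
        partial[code - 1] += s;
        visited |= (1 << code);
        tof += s * n_refr[code] / C_MM_PS;
        pos[0] += dir[0] * s; pos[1] += dir[1] * s; pos[2] += dir[2] * s;
        if (interact) { outcome = "interaction"; break; }
        // peek across the face
        int jx = ix, jy = iy, jz = iz;
        if (axis == 0) jx += sgn; else if (axis == 1) jy += sgn; else jz += sgn;
        if (jx < 0 || jy < 0 || jz < 0 || jx >= nx || jy >= ny || jz >= nz) {
            stop("packet escaped the grid bounding box without an air boundary: malformed volume");
        }
        int next = labels[jx + nx * (jy + ny * jz)];
        if (next == 0) { outcome = "surface"; break; }
        ix = jx; iy = jy; iz = jz;
        // nudge across the boundary to keep position inside the new voxel
        pos[0] += dir[0] * 1e-9; pos[1] += dir[1] * 1e-9; pos[2] += dir[2] * 1e-9;
    }
    int code_here = labels[ix + nx * (iy + ny * iz)];
    IntegerVector normal(3);
    if (outcome == "surface") normal[axis] = sgn;
    return List::create(
        _["outcome"] = outcome,
        _["position"] = NumericVector::create(pos[0], pos[1], pos[2]),
        _["direction"] = NumericVector::create(dir[0], dir[1], dir[2]),
        _["time_ps"] = tof,
        _["partial_path"] = partial,
        _["visited_mask"] = visited,
        _["voxel"] = IntegerVector::create(ix + 1, iy + 1, iz + 1),
        _["tissue"] = code_here,
        _["normal"] = normal);
}

// ---------------------------------------------------------------------------
// Full simulation kernel
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_mc(IntegerVector labels, IntegerVector dims, NumericVector voxsize,
                NumericVector mu_a, NumericVector mu_s, NumericVector g_hg,
                NumericVector n_refr,
                NumericVector src_pos, NumericVector src_dir,
                NumericMatrix det_disks,  // k x 4: x, y, z, radius
                NumericMatrix det_rings,  // m x 2: r_inner, r_outer (on source face)
                int n_photons, double seed,
                double max_time_ps, double bin_width_ps,
                bool roulette_on, double roulette_threshold,
                double roulette_survive,
                bool strict_bounds,
                bool want_absorption,
                IntegerVector ssp_detectors,   // 1-based detector indices
                bool record_paths, int max_path_records,
                bool want_fluence, int n_time_bins) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const double vx = voxsize[0], vy = voxsize[1], vz = voxsize[2];
    const size_t nvox = (size_t)nx * ny * nz;
    const int ndisk = det_disks.nrow(), nring = det_rings.nrow();
    const int ndet = ndisk + nring;

    std::vector<double> absorption(want_absorption ? nvox : 0, 0.0);
    std::vector<double> fluence(want_fluence ? nvox * (size_t)n_time_bins : 0, 0.0);

    // SSP accumulators for the requested detectors
    std::vector<int> ssp_of_det(ndet + 1, -1);
    std::vector< std::vector<double> > ssp;
    for (int i = 0; i < ssp_detectors.size(); ++i) {
        int d = ssp_detectors[i];
        if (d < 1 || d > ndet) stop("ssp detector index out of range");
        ssp_of_det[d] = (int)ssp.size();
        ssp.push_back(std::vector<double>(nvox, 0.0));
    }
    const bool need_buffer = !ssp.empty() || record_paths;

    // detection records
    std::vector<int> rec_photon, rec_det, rec_visited;
    std::vector<double> rec_w, rec_t;
    std::vector<double> rec_path[5];

    // per-photon traversal buffer (voxel linear index, segment length)
    std::vector< std::pair<int, double> > segbuf;
    List paths_out;
    std::vector<int> paths_photon;
    std::vector< std::vector< std::pair<int, double> > > paths_store;

    // conservation ledger
    double led_deposited = 0, led_exit_det = 0, led_exit_undet = 0;
    double led_roul_killed = 0, led_roul_gain = 0, led_gate = 0;
    double led_escaped = 0, led_safety = 0;

    for (int ph = 0; ph < n_photons; ++ph) {
        if ((ph & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
        uint64_t st = photon_stream(seed, ph);
        double pos[3] = {src_pos[0], src_pos[1], src_pos[2]};
        double dir[3] = {src_dir[0], src_dir[1], src_dir[2]};
        double w = 1.0, tof = 0.0;
        double partial[5] = {0, 0, 0, 0, 0};
        int visited = 0;
        if (need_buffer) segbuf.clear();

        int ix = (int)std::floor(pos[0] / vx);
        int iy = (int)std::floor(pos[1] / vy);
        int iz = (int)std::floor(pos[2] / vz);
        bool alive = true;
        long steps = 0;

        while (alive) {
            double budget = -std::log(1.0 - runif01(st));
            // ---- free path over possibly many voxels ----
            for (;;) {
                if (++steps > 20000000L) {
                    led_safety += w; alive = false; break;
                }
                if (ix < 0 || iy < 0 || iz < 0 ||
                    ix >= nx || iy >= ny || iz >= nz) {
                    if (strict_bounds)
                        stop("packet escaped the grid bounding box without an air boundary: malformed volume");
                    led_escaped += w; alive = false; break;
                }
                size_t lin = (size_t)ix + nx * ((size_t)iy + (size_t)ny * iz);
                int code = labels[lin];
                if (code == 0) {
                    // should not happen: launch checked R-side
                    led_escaped += w; alive = false; break;
                }
                double ma = mu_a[code];
                double mt = ma + mu_s[code];
                // a non-scattering voxel supports no interaction events:
                // absorption there is applied continuously (exact
                // Beer-Lambert attenuation along the segment)
                bool pureAbsorber = (mu_s[code] == 0.0);
                double rate = pureAbsorber ? 0.0 : mt;
                int axis, sgn;
                double seg = dist_to_exit(pos, dir, ix, iy, iz,
                                          vx, vy, vz, axis, sgn);
                double s;
                bool interact = false;
                if (rate > 0.0 && rate * seg >= budget) {
                    s = budget / rate;
                    interact = true;
                } else {
                    s = seg;
                    budget -= rate * s;
                }
                double t0 = tof;
                partial[code - 1] += s;
                visited |= (1 << code);
                tof += s * n_refr[code] / C_MM_PS;
                pos[0] += dir[0] * s; pos[1] += dir[1] * s; pos[2] += dir[2] * s;
                if (need_buffer && s > 0.0)
                    segbuf.push_back(std::make_pair((int)lin, s));
                if (want_fluence && s > 0.0) {
                    int bin = (int)(0.5 * (t0 + tof) / bin_width_ps);
                    if (bin >= n_time_bins) bin = n_time_bins - 1;
                    fluence[lin + nvox * (size_t)bin] += w * s;
                }
                if (pureAbsorber && ma > 0.0) {
                    double dwc = w * (1.0 - std::exp(-ma * s));
                    if (want_absorption) absorption[lin] += dwc;
                    led_deposited += dwc;
                    w -= dwc;
                }
                if (tof > max_time_ps) { led_gate += w; alive = false; break; }
                if (interact) {
                    // ---- combined interaction: deposit then scatter ----
                    double dw = w * ma / mt;
                    if (want_absorption) absorption[lin] += dw;
                    led_deposited += dw;
                    w -= dw;
                    double ct = hg_cos(runif01(st), g_hg[code]);
                    double psi = 2.0 * M_PI * runif01(st);
                    rotate_dir(dir, ct, psi);
                    break;
                }
                // ---- face crossing ----
                int jx = ix, jy = iy, jz = iz;
                if (axis == 0) jx += sgn; else if (axis == 1) jy += sgn;
                else jz += sgn;
                bool out_of_grid = (jx < 0 || jy < 0 || jz < 0 ||
                                    jx >= nx || jy >= ny || jz >= nz);
                int next = out_of_grid ? -1 :
                    labels[(size_t)jx + nx * ((size_t)jy + (size_t)ny * jz)];
                if (out_of_grid) {
                    if (strict_bounds)
                        stop("packet escaped the grid bounding box without an air boundary: malformed volume");
                    led_escaped += w; alive = false; break;
                }
                if (next == 0) {
                    // air surface: Fresnel decision at the face
                    double ci = std::fabs(dir[axis]);
                    double R = fresnel_R(ci, n_refr[code], n_refr[0]);
                    if (runif01(st) < R) {
                        dir[axis] = -dir[axis];
                        pos[0] += dir[0] * 1e-9; pos[1] += dir[1] * 1e-9;
                        pos[2] += dir[2] * 1e-9;
                        continue;
                    }
                    // exit: binary survival, full current weight leaves
                    int hit = 0;
                    for (int d = 0; d < ndisk && !hit; ++d) {
                        double dx = pos[0] - det_disks(d, 0);
                        double dy = pos[1] - det_disks(d, 1);
                        double dz = pos[2] - det_disks(d, 2);
                        double rr = det_disks(d, 3);
                        if (dx * dx + dy * dy + dz * dz <= rr * rr) hit = d + 1;
                    }
                    if (!hit && nring > 0 && axis == 2 &&
                        std::fabs(pos[2] - src_pos[2]) < 1.5 * vz) {
                        double dx = pos[0] - src_pos[0];
                        double dy = pos[1] - src_pos[1];
                        double rho = std::sqrt(dx * dx + dy * dy);
                        for (int d = 0; d < nring; ++d) {
                            if (rho >= det_rings(d, 0) && rho < det_rings(d, 1)) {
                                hit = ndisk + d + 1; break;
                            }
                        }
                    }
                    if (hit) {
                        rec_photon.push_back(ph + 1);
                        rec_det.push_back(hit);
                        rec_w.push_back(w);
                        rec_t.push_back(tof);
                        for (int l = 0; l < 5; ++l) rec_path[l].push_back(partial[l]);
                        rec_visited.push_back(visited);
                        led_exit_det += w;
                        if (need_buffer) {
                            int si = ssp_of_det[hit];
                            if (si >= 0) {
                                for (size_t k = 0; k < segbuf.size(); ++k)
                                    ssp[si][segbuf[k].first] += segbuf[k].second * w;
                            }
                            if (record_paths &&
                                (int)paths_store.size() < max_path_records) {
                                paths_store.push_back(segbuf);
                                paths_photon.push_back(ph + 1);
                            }
                        }
                    } else {
                        led_exit_undet += w;
                    }
                    alive = false;
                    break;
                }
                // tissue-tissue face: refract only on refractive-index mismatch
                if (n_refr[next] != n_refr[code]) {
                    double ci = std::fabs(dir[axis]);
                    double R = fresnel_R(ci, n_refr[code], n_refr[next]);
                    if (runif01(st) < R) {
                        dir[axis] = -dir[axis];
                        pos[0] += dir[0] * 1e-9; pos[1] += dir[1] * 1e-9;
                        pos[2] += dir[2] * 1e-9;
                        continue;
                    }
                    snell_refract(dir, axis, sgn, n_refr[code], n_refr[next]);
                }
                ix = jx; iy = jy; iz = jz;
                pos[0] += dir[0] * 1e-9; pos[1] += dir[1] * 1e-9;
                pos[2] += dir[2] * 1e-9;
            }
            if (!alive) break;
            // ---- roulette ----
            if (roulette_on && w < roulette_threshold) {
                if (runif01(st) < roulette_survive) {
                    double w_new = w / roulette_survive;
                    led_roul_gain += w_new - w;
                    w = w_new;
                } else {
                    led_roul_killed += w;
                    alive = false;
                }
            }
        }
    }

    int nrec = (int)rec_w.size();
    DataFrame det = DataFrame::create(
        _["photon"] = wrap(rec_photon),
        _["detector"] = wrap(rec_det),
        _["weight"] = wrap(rec_w),
        _["time_ps"] = wrap(rec_t),
        _["path_scalp"] = wrap(rec_path[0]),
        _["path_skull"] = wrap(rec_path[1]),
        _["path_csf"] = wrap(rec_path[2]),
        _["path_gray"] = wrap(rec_path[3]),
        _["path_white"] = wrap(rec_path[4]),
        _["visited_mask"] = wrap(rec_visited));

    NumericVector ledger = NumericVector::create(
        _["launched"] = (double)n_photons,
        _["deposited"] = led_deposited,
        _["exited_detected"] = led_exit_det,
        _["exited_undetected"] = led_exit_undet,
        _["roulette_killed"] = led_roul_killed,
        _["roulette_gain"] = led_roul_gain,
        _["gate_terminated"] = led_gate,
        _["escaped_bounds"] = led_escaped,
        _["safety_terminated"] = led_safety,
        _["n_detected"] = (double)nrec);

    List out = List::create(
        _["detections"] = det,
        _["ledger"] = ledger);
    if (want_absorption) out["absorption"] = wrap(absorption);
    if (!ssp.empty()) {
        List sl(ssp.size());
        for (size_t i = 0; i < ssp.size(); ++i) sl[i] = wrap(ssp[i]);
        out["ssp"] = sl;
    }
    if (record_paths) {
        int np = (int)paths_store.size();
        List pl(np);
        for (int i = 0; i < np; ++i) {
            int m = (int)paths_store[i].size();
            IntegerVector vox(m); NumericVector len(m);
            for (int k = 0; k < m; ++k) {
                vox[k] = paths_store[i][k].first + 1; // 1-based linear index
                len[k] = paths_store[i][k].second;
            }
            pl[i] = List::create(_["photon"] = paths_photon[i],
                                 _["voxel"] = vox, _["length_mm"] = len);
        }
        out["paths"] = pl;
    }
    if (want_fluence) out["fluence"] = wrap(fluence);
    return out;
}
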