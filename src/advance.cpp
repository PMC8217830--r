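#include <Rcpp.h>
using namespace Rcpp;

// Semi-implicit (IMEX) update of the two-region oxygen field.
//
// Tissue nodes:  P+ = [P + dt*(D lap(P) + K - (M0/k) P/(P+P50))] / (1 + dt*K/P0)
//   (the linear part of the capillary source is taken at the new time level,
//    diffusion and the Michaelis-Menten sink at the old one)
// PDMS nodes:    P+ = P + dt * D' lap(P)
// Interface node (the grid plane z = h_pdms, half PDMS / half tissue):
//   conservative balance of the two one-sided vertical fluxes D'k' and D k
//   over the composite control volume with solubility (k + k')/2, arithmetic
//   mean of D*k laterally, and tissue reaction at half weight. This makes
//   the discrete steady state exact for piecewise-linear two-layer profiles
//   and keeps the uniform reaction equilibrium an exact fixed point.
//
// The Laplacian uses second-order central differences. Zero-flux outer faces
// are mirror-symmetric (the face term is dropped); window nodes on the glass
// plane (z = 0) and, optionally, the whole top plane are held at fixed PO2.
//
// Grid layout: linear index i = x + nx*(y + ny*z); z-levels 0..n_pdms-1 are
// the PDMS region (the last of them is the interface plane when tissue lies
// above); n_pdms = 0 means an all-tissue column.
// [[Rcpp::export]]
List advance_field_cpp(NumericVector P_init, int nx, int ny, int nz,
                       LogicalVector window, double window_po2,
                       int n_pdms, double dt, double dx,
                       double D_t, double k_t, double D_p, double k_p,
                       double K, double P0cap, double P50, double Mk,
                       int nsteps, double steady_tol, bool stop_at_steady,
                       IntegerVector probes, int record_every,
                       double top_po2, bool top_fixed)
{
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (P_init.size() != n) stop("field size does not match grid");
    const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
    const double dx2 = dx * dx;

    // per-z-level coefficients: lateral / up-face / down-face diffusion
    // (already divided by the local solubility) and reaction weight
    const int iz_int = (n_pdms > 0 && n_pdms < nz) ? n_pdms - 1 : -1;
    const double k_eff = 0.5 * (k_t + k_p);
    std::vector<double> clat(nz), cup(nz), cdn(nz), rs(nz);
    for (int z = 0; z < nz; ++z) {
        if (z == iz_int) {
            clat[z] = 0.5 * (D_t * k_t + D_p * k_p) / k_eff;
            cup[z] = D_t * k_t / k_eff;
            cdn[z] = D_p * k_p / k_eff;
            rs[z] = 0.5 * k_t / k_eff;
        } else if (z < n_pdms) {
            clat[z] = cup[z] = cdn[z] = D_p;
            rs[z] = 0.0;
        } else {
            clat[z] = cup[z] = cdn[z] = D_t;
            rs[z] = 1.0;
        }
    }

    std::vector<double> A(P_init.begin(), P_init.end());
    std::vector<double> B(n);
    double *cur = A.data(), *nxt = B.data();

    const int *win = nullptr;
    std::vector<int> winv;
    if (window.size() > 0) {
        if (window.size() != (R_xlen_t)nx * ny)
            stop("window mask size must be nx*ny");
        winv.assign(window.begin(), window.end());
        win = winv.data();
    }
    // enforce the boundary values on the incoming field so an instantaneous
    // gas switch is seen by the very first step
    if (win)
        for (R_xlen_t j = 0; j < (R_xlen_t)nx * ny; ++j)
            if (win[j]) cur[j] = window_po2;
    if (top_fixed)
        for (R_xlen_t j = n - (R_xlen_t)nx * ny; j < n; ++j) cur[j] = top_po2;

    const int np = probes.size();
    int nrec_max = (record_every > 0) ? nsteps / record_every + 1 : 0;
    NumericMatrix trace(nrec_max, np);
    IntegerVector rec_steps(nrec_max);
    int nrec = 0;
    if (record_every > 0) {
        for (int p = 0; p < np; ++p) trace(0, p) = cur[probes[p]];
        rec_steps[0] = 0;
        nrec = 1;
    }

    int steps_done = 0;
    bool converged = false;
    double max_dp = NA_REAL;
    R_xlen_t bad_node = -1;
    int bad_step = -1;

    for (int step = 0; step < nsteps; ++step) {
        double mdp = 0.0;
        for (int z = 0; z < nz; ++z) {
            const double cl = clat[z] / dx2;
            const double cu = cup[z] / dx2, cd = cdn[z] / dx2;
            const double r = rs[z];
            const double denom = 1.0 + dt * r * K / P0cap;
            const bool z0 = (z == 0), ztop = (z == nz - 1);
            for (int y = 0; y < ny; ++y) {
                R_xlen_t i = sy * y + sz * z;
                const int *wrow = (z0 && win) ? win + (R_xlen_t)nx * y : nullptr;
                for (int x = 0; x < nx; ++x, ++i) {
                    if (wrow && wrow[x]) { nxt[i] = window_po2; continue; }
                    if (top_fixed && ztop) { nxt[i] = top_po2; continue; }
                    const double p = cur[i];
                    // zero-flux faces use mirror ghosts: a missing neighbour
                    // reflects the opposite one, doubling that face term
                    double lap = 0.0;
                    if (nx > 1) {
                        if (x > 0 && x < nx - 1)
                            lap += cl * (cur[i - sx] + cur[i + sx] - 2 * p);
                        else if (x == 0) lap += 2 * cl * (cur[i + sx] - p);
                        else             lap += 2 * cl * (cur[i - sx] - p);
                    }
                    if (ny > 1) {
                        if (y > 0 && y < ny - 1)
                            lap += cl * (cur[i - sy] + cur[i + sy] - 2 * p);
                        else if (y == 0) lap += 2 * cl * (cur[i + sy] - p);
                        else             lap += 2 * cl * (cur[i - sy] - p);
                    }
                    if (nz > 1) {
                        if (z > 0 && !ztop)
                            lap += cd * (cur[i - sz] - p)
                                 + cu * (cur[i + sz] - p);
                        else if (z0)     lap += 2 * cu * (cur[i + sz] - p);
                        else             lap += 2 * cd * (cur[i - sz] - p);
                    }
                    double pn;
                    if (r > 0.0)
                        pn = (p + dt * (lap + r * (K - Mk * p / (p + P50))))
                             / denom;
                    else
                        pn = p + dt * lap;
                    if (!(pn >= 0.0)) {       // catches NaN and negatives
                        if (bad_node < 0) { bad_node = i; bad_step = step; }
                        pn = p;
                    }
                    const double d = pn > p ? pn - p : p - pn;
                    if (d > mdp) mdp = d;
                    nxt[i] = pn;
                }
            }
        }
        std::swap(cur, nxt);
        ++steps_done;
        max_dp = mdp;
        if (bad_node >= 0) break;
        if (record_every > 0 && steps_done % record_every == 0) {
            for (int p = 0; p < np; ++p) trace(nrec, p) = cur[probes[p]];
            rec_steps[nrec] = steps_done;
            ++nrec;
        }
        if (stop_at_steady && mdp / dt < steady_tol) { converged = true; break; }
    }

    NumericVector out(n);
    std::copy(cur, cur + n, out.begin());
    return List::create(
        _["P"] = out,
        _["steps"] = steps_done,
        _["converged"] = converged,
        _["max_dp"] = max_dp,
        _["trace"] = trace,
        _["rec_steps"] = rec_steps,
        _["nrec"] = nrec,
        _["bad_node"] = (double)(bad_node + 1),  // 1-based; 0 = none
        _["bad_step"] = bad_step);
}
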