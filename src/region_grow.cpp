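#include <Rcpp.h>
#include <vector>
#include <deque>

using namespace Rcpp;

// Breadth-first flood fill of a binary mask from ordered seeds. Seeds are
// processed in order; a voxel reached by an earlier seed keeps that label
// (first seed wins). Connectivity 6/18/26 in 3-D collapses to 4/8 for
// single-slice masks.
// [[Rcpp::export]]
IntegerVector cpp_region_grow(LogicalVector mask, IntegerVector dims,
                              IntegerMatrix seeds, int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const size_t nvox = (size_t)nx * ny * nz;
    if (connectivity != 6 && connectivity != 18 && connectivity != 26)
        stop("connectivity must be 6, 18 or 26");

    std::vector<int> offs_dx, offs_dy, offs_dz;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (m == 0) continue;
                if (connectivity == 6 && m > 1) continue;
                if (connectivity == 18 && m > 2) continue;
                offs_dx.push_back(dx); offs_dy.push_back(dy); offs_dz.push_back(dz);
            }

    IntegerVector lab(nvox, 0);
    std::deque<size_t> queue;
    for (int s = 0; s < seeds.nrow(); ++s) {
        int sx = seeds(s, 0) - 1, sy = seeds(s, 1) - 1, sz = seeds(s, 2) - 1;
        if (sx < 0 || sy < 0 || sz < 0 || sx >= nx || sy >= ny || sz >= nz)
            stop("seed %d is outside the grid", s + 1);
        size_t lin = (size_t)sx + nx * ((size_t)sy + (size_t)ny * sz);
        if (!mask[lin])
            stop("seed %d lies on background", s + 1);
        if (lab[lin] != 0) continue; // already flooded by an earlier seed
        lab[lin] = s + 1;
        queue.clear();
        queue.push_back(lin);
        while (!queue.empty()) {
            size_t cur = queue.front(); queue.pop_front();
            int cz = (int)(cur / ((size_t)nx * ny));
            size_t rem = cur - (size_t)cz * nx * ny;
            int cy = (int)(rem / nx);
            int cx = (int)(rem % nx);
            for (size_t k = 0; k < offs_dx.size(); ++k) {
                int jx = cx + offs_dx[k], jy = cy + offs_dy[k], jz = cz + offs_dz[k];
                if (jx < 0 || jy < 0 || jz < 0 || jx >= nx || jy >= ny || jz >= nz)
                    continue;
                size_t jl = (size_t)jx + nx * ((size_t)jy + (size_t)ny * jz);
                if (mask[jl] && lab[jl] == 0) {
                    lab[jl] = s + 1;
                    queue.push_back(jl);
                }
            }
        }
    }
    return lab;
}
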