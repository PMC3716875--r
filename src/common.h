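#ifndef STRUCTSCAN_COMMON_H
#define STRUCTSCAN_COMMON_H

#include <cstdint>
#include <algorithm>

// Reserved minus-infinity sentinel for integer centi-unit scores.
// Saturating addition keeps it absorbing without floating-point -Inf.
static const int64_t NEG_SENTINEL = -(int64_t(1) << 40);

static inline int64_t sat_add(int64_t a, int64_t b) {
    if (a <= NEG_SENTINEL || b <= NEG_SENTINEL) return NEG_SENTINEL;
    return a + b;
}

static inline int64_t max2(int64_t a, int64_t b) { return a > b ? a : b; }
static inline int64_t max3(int64_t a, int64_t b, int64_t c) {
    return max2(a, max2(b, c));
}

#endif
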